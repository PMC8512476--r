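#' Confusion counts against reference IC labels
#'
#' Collapses both the automated and the reference labels to the binary
#' cardiac-related-component class (CRC = ECC or PCC merged) versus NCC, and
#' counts true/false positives/negatives with CRC as the positive class:
#' a TP is an artefactual IC correctly flagged as CRC, a FN an artefactual IC
#' retained as clean, and so on. An automated ECC against a reference PCC
#' (or vice versa) therefore counts as a TP.
#'
#' @param auto_labels automated labels: a list of `ic_label` objects or a
#'   character vector in `{ECC, PCC, NCC}`.
#' @param ref_labels reference (expert) labels, character in
#'   `{ECC, PCC, NCC}`.
#' @return An object of class `"confusion_counts"` with integer fields `tp`,
#'   `tn`, `fp`, `fn` summing to the number of compared ICs.
#' @export
build_confusion <- function(auto_labels, ref_labels) {
  to_chr <- function(x) {
    if (is.list(x)) vapply(x, `[[`, "", "label") else as.character(x)
  }
  auto <- to_chr(auto_labels)
  ref <- to_chr(ref_labels)
  if (length(auto) != length(ref))
    stop("label lists have different lengths (", length(auto), " vs ",
         length(ref), ")")
  valid <- c("ECC", "PCC", "NCC")
  if (!all(auto %in% valid) || !all(ref %in% valid))
    stop("labels must be ECC, PCC or NCC")
  a <- auto %in% c("ECC", "PCC")   # CRC after merging
  r <- ref %in% c("ECC", "PCC")
  confusion_counts(tp = sum(a & r), tn = sum(!a & !r),
                   fp = sum(a & !r), fn = sum(!a & r))
}

#' @rdname build_confusion
#' @param tp,tn,fp,fn non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_counts")
}

#' Classification scores: accuracy, FOR and corrected sensitivity
#'
#' From a confusion table with the cardiac-related components as the positive
#' class:
#' \deqn{accuracy = (TP + TN) / (TP + TN + FP + FN)}
#' \deqn{FOR = FN / (TN + FN)}
#' \deqn{sensitivity = (TPR - FPR) / (1 - FPR)}
#' with `TPR = TP/(TP+FN)` and `FPR = FP/(FP+TN)`. The sensitivity is the
#' chance-of-false-alarm-corrected recall: it reduces to the ordinary recall
#' when `FP = 0` and is negative only in the pathological case
#' `TPR < FPR`, which is flagged with a warning but never clamped. The
#' False Omission Rate is the fraction of ICs retained as clean that were
#' actually artefactual -- the clinically critical error.
#'
#' @param c a [confusion_counts()] object.
#' @return named numeric vector `c(accuracy, for_rate, sensitivity)`, full
#'   precision.
#' @examples
#' classification_scores(confusion_counts(tp = 53, tn = 362, fp = 1, fn = 4))
#' @export
classification_scores <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0) stop("accuracy undefined: no compared ICs")
  if (c$tn + c$fn == 0) stop("FOR undefined: TN + FN = 0")
  if (c$tp + c$fn == 0) stop("sensitivity undefined: TP + FN = 0")
  if (c$fp + c$tn == 0) stop("sensitivity undefined: FP + TN = 0")
  tpr <- c$tp / (c$tp + c$fn)
  fpr <- c$fp / (c$fp + c$tn)
  sens <- (tpr - fpr) / (1 - fpr)
  if (sens < 0)
    warning("negative corrected sensitivity: true-positive rate below ",
            "false-positive rate")
  c(accuracy = (c$tp + c$tn) / tot,
    for_rate = c$fn / (c$tn + c$fn),
    sensitivity = sens)
}

#' Read reference IC labels from a text table
#'
#' Expects a tab- or whitespace-separated file with columns
#' `segment`, `ic`, `label` (header optional), as produced when expert
#' annotations are supplied externally.
#'
#' @param path path to the label table.
#' @return data frame with columns `segment`, `ic`, `label`.
#' @export
read_reference_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("label", tolower(first))
  d <- if (has_header)
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  else
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("segment", "ic", "label"))
  names(d) <- tolower(names(d))
  d$label <- toupper(d$label)
  if (!all(d$label %in% c("ECC", "PCC", "NCC")))
    stop("labels must be ECC, PCC or NCC")
  d
}
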