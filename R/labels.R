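#' Parity label encoding for the six-class assessment task
#'
#' The six target classes combine the clinician-assigned FMA-UE sub-score
#' `s` (0 severe, 1 moderate, 2 normal) with the motion-phase parity `p`
#' (0 extension / reach out, 1 flexion / return) as `y = 2 s + p`. Classes
#' 0-1 therefore correspond to score 0, classes 2-3 to score 1 and classes
#' 4-5 to score 2.
#'
#' @param s FMA-UE sub-score, integer vector with values in \{0, 1, 2\}.
#' @param p Motion-phase parity, integer vector with values in \{0, 1\}.
#' @return `encode_label()` returns the class label `y` in 0..5;
#'   `decode_label()` returns a data frame with columns `s` and `p`.
#' @examples
#' encode_label(2, 1)   # 5
#' decode_label(0:5)
#' @export
encode_label <- function(s, p) {
  if (!all(s %in% 0:2)) stop("score s must be in {0, 1, 2}", call. = FALSE)
  if (!all(p %in% 0:1)) stop("parity p must be in {0, 1}", call. = FALSE)
  as.integer(2L * s + p)
}

#' @rdname encode_label
#' @param y Encoded class label, integer vector with values in 0..5.
#' @export
decode_label <- function(y) {
  if (!all(y %in% 0:5)) stop("label y must be in 0..5", call. = FALSE)
  data.frame(s = as.integer(y %/% 2L), p = as.integer(y %% 2L))
}
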