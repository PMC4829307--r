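#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rexp runif setNames lm coef pnorm cor.test
#'   wilcox.test fisher.test rpois
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# pairwise overlap length of closed intervals
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# merge closed intervals given as a data.frame(start, end); returns same shape
.merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x[, c("start", "end")])
  ir <- IRanges::reduce(IRanges::IRanges(x$start, x$end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
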