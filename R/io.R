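#' Read / write error-call and box tables (TSV interchange)
#'
#' Calls use the header `iteration category x_start x_end y_start y_end
#' resolution score tile_id status`; detector boxes use `category x1 y1
#' x2 y2 score`.
#'
#' @param calls,boxes data.frames in the respective layouts.
#' @param path a TSV path.
#' @return readers return the data.frame; writers the path, invisibly.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname writeCalls
#' @export
writeBoxes <- function(boxes, path) {
  utils::write.table(boxes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readBoxes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
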