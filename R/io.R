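#' Read and write coupling matrices as CSV
#'
#' An m x m coupling matrix is stored as a plain CSV with one row per
#' postsynaptic module and no header.
#'
#' @param C Coupling matrix.
#' @param file Path.
#' @return `read_coupling_csv` returns the matrix.
#' @export
write_coupling_csv <- function(C, file) {
  utils::write.table(as.matrix(C), file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_coupling_csv
#' @export
read_coupling_csv <- function(file) {
  M <- as.matrix(utils::read.table(file, sep = ","))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("coupling matrix must be square")
  M
}

#' Tidy CSV export of a coupled run
#'
#' One row per recorded sample, module and direction, with the unwrapped
#' phase and the velocity readout.
#'
#' @param run A `coupled_run` from [run_coupled()].
#' @param file Path.
#' @export
write_run_csv <- function(run, file) {
  m <- dim(run$theta)[2]
  dims <- dim(run$theta)[3]
  rows <- expand.grid(i = seq_along(run$t), module = seq_len(m),
                      direction = c("x", "y")[seq_len(dims)])
  d <- data.frame(
    t = run$t[rows$i],
    module = rows$module,
    direction = rows$direction,
    theta = run$theta[cbind(rows$i, rows$module,
                            as.integer(rows$direction))],
    omega = run$omega[cbind(rows$i, rows$module,
                            as.integer(rows$direction))]
  )
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
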