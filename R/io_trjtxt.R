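#' Read / write the TRJTXT v1 columnar trajectory dialect
#'
#' TRJTXT v1 is a plain-text trajectory exchange format designed for
#' bit-exact fixtures: a header line `#TRJTXT n_sites=<N> dt_ps=<dt>`,
#' then per frame a line `#FRAME t=<ps> box=<Lx> <Ly> <Lz>` followed by N
#' lines `x y z` in nm.
#'
#' @param path file path.
#' @param sites the `site_table` describing the N sites (TRJTXT carries
#'   no metadata).
#' @return `read_trjtxt()` returns a `md_trajectory`.
#' @export
read_trjtxt <- function(path, sites) {
  validate_site_table(sites)
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec(
    "^#TRJTXT n_sites=([0-9]+) dt_ps=([-0-9.eE+]+|NA)$", hdr))[[1]]
  if (length(m) != 3L)
    stop("not a TRJTXT v1 file: bad header '", hdr, "'")
  nsite <- as.integer(m[2])
  dt <- suppressWarnings(as.numeric(m[3]))
  if (nsite != nrow(sites))
    stop("TRJTXT declares ", nsite, " sites; site_table has ", nrow(sites))
  frame_at <- grep("^#FRAME ", lines)
  if (!length(frame_at)) stop("TRJTXT file contains no frames")
  nf <- length(frame_at)
  times <- numeric(nf)
  boxes <- matrix(0, nf, 3)
  arr <- array(0, c(nsite, 3, nf))
  for (i in seq_len(nf)) {
    fm <- regmatches(lines[frame_at[i]], regexec(
      "^#FRAME t=([-0-9.eE+]+) box=([-0-9.eE+]+) ([-0-9.eE+]+) ([-0-9.eE+]+)$",
      lines[frame_at[i]]))[[1]]
    if (length(fm) != 5L)
      stop("malformed #FRAME line at line ", frame_at[i])
    times[i] <- as.numeric(fm[2])
    boxes[i, ] <- as.numeric(fm[3:5])
    block <- lines[(frame_at[i] + 1L):(frame_at[i] + nsite)]
    xyz <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(xyz) != nsite)
      stop("frame ", i, " has ", nrow(xyz), " coordinate lines, expected ",
           nsite)
    arr[, , i] <- xyz
  }
  md_trajectory(sites, arr, times, boxes,
                dt = if (is.na(dt)) NULL else dt)
}

#' @rdname read_trjtxt
#' @param traj a `md_trajectory`.
#' @export
write_trjtxt <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#TRJTXT n_sites=%d dt_ps=%s", n_sites(traj),
                     num_txt(traj$dt)), con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("#FRAME t=%s box=%s %s %s",
                       num_txt(traj$times[i]), num_txt(traj$boxes[i, 1]),
                       num_txt(traj$boxes[i, 2]), num_txt(traj$boxes[i, 3])),
               con)
    xyz <- traj$coords[, , i, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    writeLines(paste(num_txt(xyz[, 1]), num_txt(xyz[, 2]),
                     num_txt(xyz[, 3])), con)
  }
  invisible(path)
}

# full-precision, locale-independent numeric formatting (deterministic bytes)
num_txt <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
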