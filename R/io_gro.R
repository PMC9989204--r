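#' Read a GRO coordinate file (single- or multi-frame)
#'
#' Parses the fixed-column GRO layout: a title line, an atom-count line,
#' one line per atom (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`, optional
#' velocities ignored), and a box line. Multi-frame files are concatenated
#' GRO blocks with identical site content. Only orthorhombic boxes are
#' accepted: a 9-number box line with any nonzero off-diagonal component
#' is rejected.
#'
#' Site metadata not present in GRO (mass, charge, electrons, polarity)
#' is taken from `sites` if supplied; otherwise a minimal `site_table`
#' is built (mass 1, charge 0, electrons `NA`, polarity `other`,
#' molecule_id from the GRO residue number).
#'
#' @param path path to a GRO file.
#' @param sites optional full `site_table` to attach (row count must
#'   match).
#' @return a list with elements `sites` (a `site_table`) and either
#'   `frame` (`md_frame`, single block) or `trajectory` (`md_trajectory`,
#'   several blocks).
#' @export
read_gro <- function(path, sites = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("not a GRO file: fewer than 3 lines")
  frames <- list()
  meta <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    title <- lines[pos]
    natom <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natom) || natom <= 0L)
      stop("malformed atom count on line ", pos + 1L, ": '",
           lines[pos + 1L], "'")
    box_line_idx <- pos + 2L + natom
    if (box_line_idx > length(lines))
      stop("declared atom count (", natom, ") on line ", pos + 1L,
           " exceeds lines present in file")
    atom_lines <- lines[(pos + 2L):(pos + 1L + natom)]
    bad <- which(nchar(atom_lines) < 44L)
    if (length(bad))
      stop("malformed atom line at line ", pos + 1L + bad[1],
           " (too short for GRO fixed columns); declared atom count ",
           "may disagree with lines present")
    box <- parse_gro_box(lines[box_line_idx], box_line_idx)
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
      stop("non-numeric coordinate field in GRO block starting at line ", pos)
    if (is.null(meta)) {
      meta <- list(
        resid = as.integer(substr(atom_lines, 1, 5)),
        resname = trimws(substr(atom_lines, 6, 10)),
        name = trimws(substr(atom_lines, 11, 15))
      )
    }
    frames[[length(frames) + 1L]] <-
      md_frame(cbind(x, y, z), box, time = gro_title_time(title),
               title = title)
    pos <- box_line_idx + 1L
  }
  natom <- nrow(frames[[1]]$coords)
  if (is.null(sites)) {
    sites <- site_table(site_name = meta$name, residue_name = meta$resname,
                        molecule_id = meta$resid)
  } else {
    validate_site_table(sites)
    if (nrow(sites) != natom)
      stop("supplied site_table has ", nrow(sites), " sites but file has ",
           natom)
  }
  if (length(frames) == 1L) {
    list(sites = sites, frame = frames[[1]])
  } else {
    times <- vapply(frames, `[[`, numeric(1), "time")
    if (any(is.na(times)) || any(diff(times) <= 0))
      times <- seq_along(frames) - 1  # fall back to frame index as ps
    arr <- array(0, c(natom, 3, length(frames)))
    boxes <- matrix(0, length(frames), 3)
    for (i in seq_along(frames)) {
      if (nrow(frames[[i]]$coords) != natom)
        stop("frame ", i, " has a different atom count")
      arr[, , i] <- frames[[i]]$coords
      boxes[i, ] <- frames[[i]]$box
    }
    list(sites = sites,
         trajectory = md_trajectory(sites, arr, times, boxes))
  }
}

# GRO convention: trailing "t= <ps>" in the title carries the frame time
gro_title_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) as.numeric(sub("t=\\s*", "", m)) else NA_real_
}

parse_gro_box <- function(line, lineno) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (any(is.na(v)) || !(length(v) %in% c(3L, 9L)))
    stop("malformed box line at line ", lineno, ": '", line, "'")
  if (length(v) == 9L && any(v[4:9] != 0))
    stop("unsupported box at line ", lineno,
         ": nonzero off-diagonal components (triclinic boxes are not",
         " supported)")
  box <- v[1:3]
  if (any(box <= 0)) stop("non-positive box edge at line ", lineno)
  box
}

#' Write a frame as a GRO file
#'
#' Writes fixed-column GRO with 3-decimal nm positions. Velocities are
#' never written. Appending allows building multi-frame files.
#'
#' @param sites a `site_table` (residue/atom names and molecule ids feed
#'   the GRO columns).
#' @param frame a `md_frame`.
#' @param path output path.
#' @param append append as an extra block (multi-frame GRO).
#' @return `path`, invisibly.
#' @export
write_gro <- function(sites, frame, path, append = FALSE) {
  validate_site_table(sites)
  n <- nrow(sites)
  if (n != nrow(frame$coords))
    stop("site_table and frame disagree on site count")
  if (n > 99999L)
    stop("GRO fixed fields cannot hold more than 99,999 sites (got ", n, ")")
  resid <- sites$molecule_id %% 100000L
  serial <- (sites$site_id + 1L) %% 100000L
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  resid, substr(sites$residue_name, 1, 5),
                  substr(sites$site_name, 1, 5), serial,
                  frame$coords[, 1], frame$coords[, 2], frame$coords[, 3])
  title <- if (!is.null(frame$title)) frame$title else
    sprintf("bilayr frame t= %.6g", frame$time)
  if (is.na(gro_title_time(title)))
    title <- sprintf("%s t= %.6g", title, frame$time)
  out <- c(title, sprintf("%5d", n), body,
           sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                   frame$box[3]))
  con <- file(path, open = if (append) "at" else "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write a trajectory as a multi-frame GRO file
#' @param traj a `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro_trajectory <- function(traj, path) {
  for (i in seq_len(n_frames(traj)))
    write_gro(traj$sites, get_frame(traj, i), path, append = i > 1L)
  invisible(path)
}
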