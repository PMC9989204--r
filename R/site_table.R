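#' Per-site static metadata table
#'
#' A `site_table` holds one row per interaction site (atom or
#' coarse-grained bead): identity, residue/molecule membership, mass,
#' charge, electron count, a polarity class used by selections and contact
#' analyses, and (for acyl-chain sites) the chain label and 1-based carbon
#' position counted from the carbonyl end.
#'
#' @param site_name character, site (atom/bead) names.
#' @param residue_name character, residue names (recycled).
#' @param molecule_id integer, molecule membership (recycled).
#' @param mass numeric, unified atomic mass units; must be > 0.
#' @param charge numeric, elementary-charge units.
#' @param electrons numeric, electron counts (>= 0); may be `NA` for
#'   coarse-grained beads, in which case electron-weighted profiles refuse
#'   the table.
#' @param polarity_class character, one of polar, apolar, phosphate,
#'   headgroup_amine, headgroup_carboxylate, hydroxyl, water, ion, other.
#' @param chain_label optional character, one of sn1, sn2, guest_chain1,
#'   guest_chain2, sterol_body; `NA` for non-chain sites.
#' @param chain_position optional 1-based integer carbon index counted in
#'   order from the carbonyl group; requires a `chain_label`.
#'
#' @return A `data.frame` of class `site_table` with a 0-based, contiguous
#'   `site_id` column first.
#' @export
site_table <- function(site_name, residue_name, molecule_id,
                       mass = 1, charge = 0, electrons = NA_real_,
                       polarity_class = "other",
                       chain_label = NA_character_,
                       chain_position = NA_integer_) {
  n <- length(site_name)
  if (n == 0L) stop("site_table must contain at least one site")
  tab <- data.frame(
    site_id = 0:(n - 1L),
    site_name = as.character(site_name),
    residue_name = rep_len(as.character(residue_name), n),
    molecule_id = rep_len(as.integer(molecule_id), n),
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    electrons = rep_len(as.numeric(electrons), n),
    polarity_class = rep_len(as.character(polarity_class), n),
    chain_label = rep_len(as.character(chain_label), n),
    chain_position = rep_len(as.integer(chain_position), n),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("site_table", "data.frame")
  validate_site_table(tab)
}

#' Validate a site table
#'
#' Checks the structural invariants: contiguous 0-based `site_id`, positive
#' masses, non-negative electron counts, known polarity classes, and that
#' every site carrying a `chain_position` also carries a `chain_label`.
#'
#' @param tab a `site_table`.
#' @return `tab`, invisibly unchanged, or an error.
#' @export
validate_site_table <- function(tab) {
  req <- c("site_id", "site_name", "residue_name", "molecule_id", "mass",
           "charge", "electrons", "polarity_class", "chain_label",
           "chain_position")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("site_table missing columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(tab)
  if (n == 0L) stop("site_table must contain at least one site")
  if (!identical(as.integer(tab$site_id), 0:(n - 1L)))
    stop("site_id values must be unique and contiguous from 0")
  if (any(!is.finite(tab$mass)) || any(tab$mass <= 0))
    stop("all site masses must be finite and > 0")
  if (any(tab$electrons < 0, na.rm = TRUE))
    stop("electron counts must be >= 0")
  bad <- setdiff(unique(tab$polarity_class), POLARITY_CLASSES)
  if (length(bad))
    stop("unknown polarity_class: ", paste(bad, collapse = ", "))
  badlab <- setdiff(unique(tab$chain_label[!is.na(tab$chain_label)]),
                    CHAIN_LABELS)
  if (length(badlab))
    stop("unknown chain_label: ", paste(badlab, collapse = ", "))
  orphan <- !is.na(tab$chain_position) & is.na(tab$chain_label)
  if (any(orphan))
    stop("sites with a chain_position must have a chain_label (site_id ",
         paste(tab$site_id[orphan], collapse = ", "), ")")
  invisible(tab)
}

#' Read / write a site table as TSV
#'
#' The on-disk dialect is a tab-separated table with the exact header
#' `site_id site_name residue_name molecule_id mass charge electrons
#' polarity_class chain_label chain_position`; missing chain fields are
#' the string `NA`.
#'
#' @param path file path.
#' @return `read_site_table()` returns a validated `site_table`.
#' @export
read_site_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "integer", "numeric", "numeric",
                                   "numeric", "character", "character",
                                   "integer"),
                    stringsAsFactors = FALSE)
  class(tab) <- c("site_table", "data.frame")
  validate_site_table(tab)
  tab
}

#' @rdname read_site_table
#' @param tab a `site_table`.
#' @export
write_site_table <- function(tab, path) {
  validate_site_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.site_table <- function(x, ...) {
  cat("site_table:", nrow(x), "sites,",
      length(unique(x$molecule_id)), "molecules,",
      length(unique(x$residue_name)), "residue types\n")
  NextMethod()
}
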