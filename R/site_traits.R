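# Binary residue-trait extraction from a protein MSA at the column homologous
# to a reference residue (e.g. the Asp of the human alpha-subunit Na+ site).

#' Read an aligned protein FASTA into a protein MSA object
#'
#' @param file FASTA path, or a named character vector of aligned sequences.
#' @return Named uppercase character vector of equal-length rows, class
#'   `protein_msa`.
#' @export
read_protein_msa <- function(file) {
  if (is.character(file) && length(file) == 1L && file.exists(file)) {
    ss <- Biostrings::readAAStringSet(file)
    seqs <- setNames(as.character(ss), names(ss))
  } else {
    seqs <- file
  }
  protein_msa(seqs)
}

#' @rdname read_protein_msa
#' @param seqs Named character vector of aligned rows.
#' @export
protein_msa <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("MSA records need unique ids")
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("MSA rows must have equal length")
  structure(seqs, class = "protein_msa")
}

#' Define the site of interest relative to a reference sequence
#'
#' @param ref_id Reference record id in the MSA.
#' @param position 1-based ungapped residue position in the reference.
#' @param residue Target amino acid (single letter, default `"D"` for Asp).
#' @param window Missing-region window in alignment columns (default 5):
#'   a gap/`X` site column with only gaps/`X` within `+/- window` columns is
#'   scored `unknown`.
#' @export
site_definition <- function(ref_id, position, residue = "D", window = 5L) {
  stopifnot(position >= 1, nchar(residue) == 1L)
  if (!toupper(residue) %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    stop("target residue must be a standard amino acid")
  structure(list(ref_id = ref_id, position = as.integer(position),
                 residue = toupper(residue), window = as.integer(window)),
            class = "site_definition")
}

#' Map a reference residue position to an alignment column
#'
#' Returns the 1-based alignment column holding the `position`-th non-gap
#' character of the reference row.
#'
#' @param msa A [protein_msa()].
#' @param site A [site_definition()].
#' @export
map_reference_position <- function(msa, site) {
  stopifnot(inherits(msa, "protein_msa"), inherits(site, "site_definition"))
  if (!site$ref_id %in% names(msa))
    stop("reference sequence '", site$ref_id, "' not in MSA")
  chars <- strsplit(unclass(msa)[[site$ref_id]], "")[[1]]
  nongap <- cumsum(chars != "-")
  col <- match(site$position, nongap)
  if (is.na(col))
    stop("position ", site$position, " beyond ungapped reference length ",
         max(nongap))
  col
}

#' Assign present/absent/unknown traits from the mapped alignment column
#'
#' Per record: the target residue scores `present`; any other standard amino
#' acid scores `absent`; `X` (or the ambiguity codes `B`, `Z`, `J`) scores
#' `unknown`; a gap scores `unknown` when the whole `+/- window` neighborhood
#' is gaps/`X` (sequence missing over the region), otherwise it is treated as
#' a true in-frame deletion and scored by `lone_gap` (default `"absent"`).
#'
#' @inheritParams map_reference_position
#' @param lone_gap `"absent"` (default) or `"unknown"`: the call for a gap at
#'   the site flanked by real residues.
#' @return A [trait_table()] over the MSA record ids.
#' @export
assign_traits <- function(msa, site, lone_gap = c("absent", "unknown")) {
  lone_gap <- match.arg(lone_gap)
  col <- map_reference_position(msa, site)
  seqs <- unclass(msa)
  L <- nchar(seqs[[1]])
  win <- max(1L, col - site$window):min(L, col + site$window)
  states <- vapply(seqs, function(s) {
    ch <- substr(s, col, col)
    if (ch == site$residue) return("present")
    if (ch %in% c("X", "B", "Z", "J")) return("unknown")
    if (ch == "-") {
      neigh <- strsplit(substr(s, min(win), max(win)), "")[[1]]
      if (all(neigh %in% c("-", "X"))) return("unknown")
      return(lone_gap)
    }
    "absent"
  }, character(1))
  trait_table(names(seqs), unname(states))
}

#' Tabulate trait states per partition
#'
#' @param traits A [trait_table()].
#' @param partition Named character vector taxon -> partition label
#'   (e.g. `"alpha"`/`"delta"`), covering every taxon in `traits`.
#' @return Matrix with one row per partition and columns
#'   `present`, `absent`, `unknown`.
#' @export
trait_census <- function(traits, partition) {
  st <- unclass(traits)
  miss <- setdiff(names(st), names(partition))
  if (length(miss))
    stop("taxa without a partition label: ", paste(miss, collapse = ", "))
  labs <- sort(unique(partition[names(st)]))
  out <- matrix(0L, nrow = length(labs), ncol = 3,
                dimnames = list(labs, c("present", "absent", "unknown")))
  if (length(st) == 0L) return(out)
  tab <- table(factor(partition[names(st)], levels = labs),
               factor(st, levels = c("present", "absent", "unknown")))
  out[] <- as.integer(tab)
  out
}
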