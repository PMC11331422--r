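# MG94xHKY codon model over the 61 sense codons of the standard genetic
# code, with F3x4 equilibrium frequencies. The generator separates into
# synonymous and nonsynonymous parts so site models Q = alpha*Rsyn + beta*Rnon
# share one normalization fixed at the global (nuisance) fit.

.NUC <- c("T", "C", "A", "G")

# cached codon bookkeeping: sense codons, amino acids, and all single-nt
# neighbor pairs with their position, target nucleotide, ts/tv and syn flags
.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  all64 <- as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[all64]
  sense <- all64[aa != "*"]
  aa <- aa[match(sense, all64)]
  n <- length(sense)  # 61
  cm <- do.call(rbind, strsplit(sense, ""))
  pairs <- list(i = integer(0), j = integer(0), pos = integer(0),
                target = character(0), is_ts = logical(0), is_syn = logical(0))
  ts_pair <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffs <- which(cm[i, ] != cm[j, ])
    if (length(diffs) != 1L) next
    p <- diffs
    pairs$i <- c(pairs$i, i); pairs$j <- c(pairs$j, j)
    pairs$pos <- c(pairs$pos, p)
    pairs$target <- c(pairs$target, cm[j, p])
    pairs$is_ts <- c(pairs$is_ts, ts_pair(cm[i, p], cm[j, p]))
    pairs$is_syn <- c(pairs$is_syn, aa[i] == aa[j])
  }
  .codon_env$tab <- list(codons = sense, aa = aa, codon_mat = cm,
                         pairs = as.data.frame(pairs,
                                               stringsAsFactors = FALSE))
  .codon_env$tab
}

#' Sense codons of the standard genetic code (n = 61)
#' @export
sense_codons <- function() .codon_tables()$codons

#' F3x4 codon equilibrium frequencies from observed nucleotide counts
#'
#' Position-specific nucleotide frequencies are tallied over all non-gap,
#' unambiguous codons; codon frequencies are the per-position products
#' renormalized over the 61 sense codons (stop-codon mass discarded).
#'
#' @param seqs Character vector of in-frame nucleotide sequences (gaps
#'   allowed as `-`).
#' @param floor Lower bound applied to each position-specific nucleotide
#'   frequency before renormalization (default 1e-4), so that rare or
#'   unobserved nucleotides never produce a structurally zero codon
#'   frequency (which would make the generator non-reversible).
#' @return List with `pi_pos` (3 x 4 matrix over T,C,A,G) and `pi_codon`
#'   (length-61 vector summing to one).
#' @export
f3x4_frequencies <- function(seqs, floor = 1e-4) {
  tab <- .codon_tables()
  counts <- matrix(0, nrow = 3, ncol = 4,
                   dimnames = list(NULL, .NUC))
  for (s in toupper(seqs)) {
    n <- nchar(s) %/% 3
    for (k in seq_len(n)) {
      cod <- substr(s, 3 * k - 2, 3 * k)
      ch <- strsplit(cod, "")[[1]]
      if (!all(ch %in% .NUC)) next
      for (p in 1:3) counts[p, ch[p]] <- counts[p, ch[p]] + 1
    }
  }
  if (any(rowSums(counts) == 0)) stop("no unambiguous codons to count")
  pi_pos <- counts / rowSums(counts)
  pi_pos <- pmax(pi_pos, floor)
  pi_pos <- pi_pos / rowSums(pi_pos)
  cm <- tab$codon_mat
  pc <- unname(pi_pos[1, cm[, 1]] * pi_pos[2, cm[, 2]] * pi_pos[3, cm[, 3]])
  list(pi_pos = pi_pos, pi_codon = pc / sum(pc))
}

#' Synonymous and nonsynonymous parts of the MG94xHKY generator
#'
#' Off-diagonal rate i->j is zero unless codons differ at exactly one
#' nucleotide; a single-nucleotide change gets `kappa` when it is a
#' transition, times the F3x4 frequency of the target nucleotide at the
#' changed position. Rows of each part sum to zero, so
#' `Q = alpha * Rsyn + beta * Rnon` is a proper generator for any site rates.
#'
#' @param kappa Transition:transversion rate ratio (> 0).
#' @param pi_pos 3 x 4 position-specific nucleotide frequencies (T,C,A,G).
#' @return List `Rsyn`, `Rnon` (61 x 61) and `pi_codon`.
#' @export
mg94_parts <- function(kappa, pi_pos) {
  stopifnot(kappa > 0)
  if (any(pi_pos <= 0))
    stop("invalid frequency vector: position frequencies must be positive")
  tab <- .codon_tables()
  n <- length(tab$codons)
  Rsyn <- matrix(0, n, n)
  Rnon <- matrix(0, n, n)
  pr <- tab$pairs
  rate <- ifelse(pr$is_ts, kappa, 1) *
    pi_pos[cbind(pr$pos, match(pr$target, .NUC))]
  syn <- pr$is_syn
  Rsyn[cbind(pr$i[syn], pr$j[syn])] <- rate[syn]
  Rnon[cbind(pr$i[!syn], pr$j[!syn])] <- rate[!syn]
  diag(Rsyn) <- -rowSums(Rsyn)
  diag(Rnon) <- -rowSums(Rnon)
  cm <- tab$codon_mat
  pc <- unname(pi_pos[1, cm[, 1]] * pi_pos[2, cm[, 2]] * pi_pos[3, cm[, 3]])
  list(Rsyn = Rsyn, Rnon = Rnon, pi_codon = pc / sum(pc))
}

#' MG94xHKY generator for given site rates
#'
#' @inheritParams mg94_parts
#' @param alpha,beta Synonymous and nonsynonymous site rates (>= 0).
#' @param normalize `TRUE` scales the generator to one expected substitution
#'   per unit time at stationarity; a number divides by that constant
#'   instead (used to share the global normalization across site models).
#' @return 61 x 61 generator with rows summing to zero, time-reversible with
#'   respect to the F3x4 codon frequencies.
#' @export
mg94_generator <- function(kappa, alpha, beta, pi_pos, normalize = FALSE) {
  parts <- mg94_parts(kappa, pi_pos)
  Q <- alpha * parts$Rsyn + beta * parts$Rnon
  if (isTRUE(normalize)) {
    Q <- Q / .mg94_rate(Q, parts$pi_codon)
  } else if (is.numeric(normalize)) {
    Q <- Q / normalize
  }
  attr(Q, "pi_codon") <- parts$pi_codon
  Q
}

.mg94_rate <- function(Q, pi) -sum(pi * diag(Q))

# ---- codon alignment container ---------------------------------------------

#' In-frame codon alignment with partition labels and a tree
#'
#' @param seqs Named character vector of equal-length in-frame DNA sequences
#'   (gap codon `---`; ambiguous codons become missing data).
#' @param tree `phylo` whose tip labels match the sequence ids.
#' @param partition Named character vector id -> partition label
#'   (`"alpha"`/`"delta"`), covering all records.
#' @param site_labels Optional labels for the codon sites (e.g. reference
#'   coordinates of binding-site residues).
#' @return `codon_alignment` object: integer state matrix (`n_seq x n_site`,
#'   0-based codon index, -1 for gap/ambiguous), frequencies inputs, tree.
#' @export
codon_alignment <- function(seqs, tree, partition, site_labels = NULL) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences need unique ids")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (L %% 3 != 0L) stop("sequence length not a multiple of 3")
  n_site <- L %/% 3
  if (!setequal(tree$tip.label, names(seqs)))
    stop("tree tips and sequence ids must match")
  miss <- setdiff(names(seqs), names(partition))
  if (length(miss)) stop("records without a partition label: ",
                         paste(miss, collapse = ", "))
  tab <- .codon_tables()
  states <- matrix(-1L, nrow = length(seqs), ncol = n_site,
                   dimnames = list(names(seqs), NULL))
  stops <- setdiff(as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0)),
                   tab$codons)
  for (r in seq_along(seqs)) {
    cods <- substring(seqs[r], 3 * seq_len(n_site) - 2, 3 * seq_len(n_site))
    if (any(cods %in% stops))
      stop("stop codon in sequence '", names(seqs)[r], "'")
    idx <- match(cods, tab$codons)
    states[r, !is.na(idx)] <- idx[!is.na(idx)] - 1L
  }
  if (is.null(site_labels)) site_labels <- as.character(seq_len(n_site))
  structure(list(ids = names(seqs), seqs = seqs, states = states,
                 tree = tree, partition = partition[names(seqs)],
                 site_labels = site_labels, n_site = n_site),
            class = "codon_alignment")
}

#' Read a codon alignment from an in-frame FASTA file
#'
#' @param file FASTA path.
#' @inheritParams codon_alignment
#' @export
read_codon_fasta <- function(file, tree, partition, site_labels = NULL) {
  ss <- Biostrings::readDNAStringSet(file)
  codon_alignment(setNames(as.character(ss), names(ss)), tree, partition,
                  site_labels)
}

# edge classes for the partition contrast: an edge is "delta" iff every tip
# below it is a delta record, otherwise "alpha" (clade stems included)
.partition_edge_classes <- function(aln) {
  delta_taxa <- names(aln$partition)[aln$partition == "delta"]
  spec <- branch_class_spec(list(list(class = "delta", taxa = delta_taxa)),
                            default = "alpha")
  tag_branches(aln$tree, spec)$branch.class
}
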