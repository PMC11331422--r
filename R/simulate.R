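# Seed-reproducible simulators for every input class: trees with a tagged
# delta clade, binary traits under the class-rate CTMC, codon alignments
# under MG94xHKY with partition-specific omega, voltage-clamp traces, and
# expression count tables. All are pure functions of (spec, seed).

#' Simulate a Yule/birth-death tree with a tagged delta clade
#'
#' Tips are labeled `t1..tn`. When `delta_fraction` is given, the internal
#' node (other than the root) whose descendant tip count is closest to
#' `delta_fraction * n_tips` is picked deterministically (smallest node id on
#' ties) and its clade -- stem branch included -- is tagged class `"delta"`;
#' all other branches get class `"alpha"`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth Speciation rate; with death 0 the expected total tree length
#'   is roughly `(n_tips - 1) / birth`. Default 0.2 gives trait simulations
#'   tens to hundreds of gain/loss events at the rates studied here.
#' @param death Extinction rate (default 0).
#' @param delta_fraction Target fraction of tips inside the delta clade.
#' @param total_length Optional rescale of branch lengths so they sum to
#'   this value (useful for codon simulations at deep divergence).
#' @param seed Optional integer seed.
#' @return `phylo` with `branch.class` and a `delta_tips` attribute.
#' @export
simulate_tree <- function(n_tips, birth = 0.2, death = 0,
                          delta_fraction = NULL, total_length = NULL,
                          seed = NULL) {
  if (n_tips < 3) stop("need n_tips >= 3")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  if (!is.null(total_length))
    tree$edge.length <- tree$edge.length *
      (total_length / sum(tree$edge.length))
  if (!is.null(delta_fraction)) {
    sets <- .node_tip_sets(tree)
    nt <- ape::Ntip(tree)
    internal <- setdiff(seq_along(sets), c(seq_len(nt), nt + 1L))
    sizes <- lengths(sets[internal])
    pick <- internal[which.min(abs(sizes - delta_fraction * n_tips))]
    delta_tips <- sets[[pick]]
    tree <- tag_branches(tree, branch_class_spec(
      list(list(class = "delta", taxa = delta_tips)), default = "alpha"))
    attr(tree, "delta_tips") <- delta_tips
  } else {
    tree$branch.class <- rep("alpha", nrow(tree$edge))
  }
  tree
}

#' Forward-simulate a binary trait along a tagged tree
#'
#' The root state is drawn from the model's root prior; each branch is then
#' simulated by exact event-driven CTMC sampling (exponential waiting times
#' between state flips) under the branch class's (gain, loss) rates.
#'
#' @param tree Tagged `phylo`.
#' @param model A [trait_model()].
#' @param seed Optional integer seed.
#' @return A [trait_table()] over the tips, with the full node-state vector
#'   in attribute `node_states`.
#' @export
simulate_traits <- function(tree, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  arrcls <- tree$branch.class
  if (is.null(arrcls)) arrcls <- rep(model$default_class, nrow(tree$edge))
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  states <- integer(nn)
  rp <- .root_prior_vec(model)
  states[nt + 1L] <- sample(c(0L, 1L), 1, prob = rp)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    len <- tree$edge.length[i]
    loss <- if (arrcls[i] == model$delta_class && is_dependent(model))
      model$q10_delta else model$q10
    s <- states[p]; t <- 0
    repeat {
      rate <- if (s == 0L) model$q01 else loss
      w <- rexp(1, rate)
      if (t + w > len) break
      t <- t + w
      s <- 1L - s
    }
    states[ch] <- s
  }
  out <- trait_table(tree$tip.label,
                     c("absent", "present")[states[seq_len(nt)] + 1L])
  attr(out, "node_states") <- states
  out
}

#' Simulate a codon alignment under MG94xHKY with partition-specific omega
#'
#' Sites evolve independently; branches tagged `"delta"` use the site's
#' delta-partition omega, all others the alpha-partition omega. The chain
#' lives on the 61 sense codons, so no stop codon is ever emitted. The
#' per-branch generators share the normalization of the `omega = 1` model,
#' so branch lengths are in expected substitutions per codon at neutrality.
#'
#' @param tree Tagged `phylo` (see [simulate_tree()]).
#' @param n_sites Number of codon sites.
#' @param kappa Transition:transversion ratio.
#' @param omega_alpha,omega_delta Per-site dN/dS for the two branch classes
#'   (scalars or length-`n_sites` vectors).
#' @param pi_pos 3 x 4 position-specific nucleotide frequencies (default
#'   uniform).
#' @param seed Optional integer seed.
#' @return A [codon_alignment()] whose partition labels mark tips inside the
#'   delta clade.
#' @export
simulate_codon_alignment <- function(tree, n_sites, kappa = 2.5,
                                     omega_alpha = 0.5, omega_delta = 0.5,
                                     pi_pos = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pi_pos))
    pi_pos <- matrix(0.25, 3, 4, dimnames = list(NULL, .NUC))
  omega_alpha <- rep_len(omega_alpha, n_sites)
  omega_delta <- rep_len(omega_delta, n_sites)
  tree <- ape::reorder.phylo(tree, "cladewise")
  cls <- tree$branch.class
  if (is.null(cls)) cls <- rep("alpha", nrow(tree$edge))
  parts <- mg94_parts(kappa, pi_pos)
  pi <- parts$pi_codon
  norm <- .mg94_rate(parts$Rsyn + parts$Rnon, pi)
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  groups <- split(seq_len(n_sites),
                  paste(omega_alpha, omega_delta, sep = "|"))
  states <- matrix(0L, nrow = nn, ncol = n_sites)
  states[nt + 1L, ] <- sample.int(61L, n_sites, replace = TRUE, prob = pi)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    len <- tree$edge.length[i]
    for (g in groups) {
      om <- if (cls[i] == "delta") omega_delta[g[1]] else omega_alpha[g[1]]
      Q <- (parts$Rsyn + om * parts$Rnon) / norm
      P <- codon_pmat_cpp(Q, pi, len)
      for (s in g)
        states[ch, s] <- sample.int(61L, 1, prob = P[states[p, s], ])
    }
  }
  codons <- sense_codons()
  seqs <- vapply(seq_len(nt),
                 function(v) paste(codons[states[v, ]], collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  delta_tips <- attr(tree, "delta_tips")
  if (is.null(delta_tips)) {
    pend <- match(seq_len(nt), tree$edge[, 2])
    delta_tips <- tree$tip.label[cls[pend] == "delta"]
  }
  partition <- setNames(ifelse(tree$tip.label %in% delta_tips,
                               "delta", "alpha"), tree$tip.label)
  codon_alignment(seqs, tree, partition)
}

#' Simulate a voltage-clamp trace with the peak / decay / amiloride shape
#'
#' Baseline until `t_switch`, an instantaneous step to `I_peak`, a single
#' exponential decay (time constant `tau`, the ~2-3 s gating-limited decay)
#' toward `I_ss`, then a fast relaxation to `I_amil` after `t_amiloride`,
#' plus Gaussian noise.
#'
#' @param I_baseline,I_peak,I_ss,I_amil Currents (microamperes, signed).
#' @param tau Decay time constant in seconds (default 2.5).
#' @param t_switch,t_amiloride,duration Event times and record length (s).
#' @param rate Sampling rate in Hz (default 10).
#' @param noise_sd Gaussian noise sd (microamperes).
#' @param seed Optional integer seed.
#' @return A [current_trace()] with the specified SSI in attribute
#'   `ssi_true`.
#' @export
simulate_trace <- function(I_baseline = -0.2, I_peak = -10, I_ss = -4,
                           I_amil = -0.5, tau = 2.5, t_switch = 10,
                           t_amiloride = 80, duration = 100, rate = 10,
                           noise_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = 1 / rate)
  cc <- numeric(length(tt))
  # the peak is reached one sample after the switch so the sampled extremum
  # equals I_peak exactly on noiseless traces
  t_pk <- t_switch + 1 / rate
  pre <- tt <= t_switch
  rise <- tt > t_switch & tt < t_pk
  mid <- tt >= t_pk & tt < t_amiloride
  post <- tt >= t_amiloride
  cc[pre] <- I_baseline
  cc[rise] <- I_baseline + (I_peak - I_baseline) *
    (tt[rise] - t_switch) / (1 / rate)
  cc[mid] <- I_ss + (I_peak - I_ss) * exp(-(tt[mid] - t_pk) / tau)
  I_at_amil <- I_ss + (I_peak - I_ss) * exp(-(t_amiloride - t_pk) / tau)
  cc[post] <- I_amil + (I_at_amil - I_amil) *
    exp(-(tt[post] - t_amiloride) / 0.5)
  if (noise_sd > 0) cc <- cc + rnorm(length(cc), sd = noise_sd)
  tr <- current_trace(tt, cc, t_switch = t_switch,
                      t_amiloride = t_amiloride)
  attr(tr, "ssi_true") <- (I_peak - I_ss) / (I_peak - I_amil)
  tr
}

#' Simulate an expression count table with known expressed/background truth
#'
#' Expressed genes get true RPKM values well above the 0.3 threshold
#' (`4 + lognormal`), background genes well below (uniform on
#' `[0, 0.15]`); counts are Poisson draws around
#' `rpkm * length/1e3 * total/1e6` (or exact rounding when
#' `sampling = "deterministic"`).
#'
#' @param n_genes Number of genes.
#' @param expressed_fraction Fraction of genes truly expressed.
#' @param library_total Total mapped reads (default 5e6).
#' @param length_range Feature length range in bp.
#' @param sampling `"poisson"` or `"deterministic"`.
#' @param seed Optional integer seed.
#' @return List `counts`, `lengths`, `library_total`, `gene_ids`, and a
#'   `truth` data frame with the designed RPKM and expressed label.
#' @export
simulate_counts <- function(n_genes, expressed_fraction = 0.7,
                            library_total = 5e6,
                            length_range = c(500, 5000),
                            sampling = c("poisson", "deterministic"),
                            seed = NULL) {
  sampling <- match.arg(sampling)
  if (!is.null(seed)) set.seed(seed)
  n_expr <- round(expressed_fraction * n_genes)
  expressed <- seq_len(n_genes) <= n_expr
  rpkm <- numeric(n_genes)
  rpkm[expressed] <- 4 + rlnorm(n_expr, meanlog = log(20), sdlog = 1)
  rpkm[!expressed] <- runif(n_genes - n_expr, 0, 0.15)
  lengths <- round(runif(n_genes, length_range[1], length_range[2]))
  lambda <- rpkm * (lengths / 1e3) * (library_total / 1e6)
  counts <- if (sampling == "poisson") rpois(n_genes, lambda)
            else round(lambda)
  gene_ids <- paste0("g", seq_len(n_genes))
  list(counts = counts, lengths = lengths, library_total = library_total,
       gene_ids = gene_ids,
       truth = data.frame(gene = gene_ids, rpkm_true = rpkm,
                          expressed_true = expressed))
}
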