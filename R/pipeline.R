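# End-to-end orchestration: trait-model comparison with ancestral scans,
# the selection (FEL/Contrast-FEL) pipeline, and the physiology pipeline.
# Configs are plain lists or JSON files; all randomness flows from one
# top-level seed through per-stage derived seeds.

#' Derive a stage seed from the top-level seed
#'
#' Deterministic, stage-isolated and kept below 2^31.
#' @param seed Integer top-level seed.
#' @param stage Stage name.
#' @export
derive_seed <- function(seed, stage) {
  code <- utf8ToInt(stage)
  as.integer((as.numeric(seed) * 1009 + sum(code * seq_along(code))) %%
               2147483000) + 1L
}

#' Read a pipeline config from JSON (or pass a list through)
#' @param config Path to a JSON file or a list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

.cfg_tree <- function(config) {
  if (!is.null(config$tree) && inherits(config$tree, "phylo"))
    return(config$tree)
  if (!is.null(config$tree_file)) return(read_newick(file = config$tree_file))
  if (!is.null(config$tree_newick)) return(read_newick(text = config$tree_newick))
  stop("config error: no tree given (tree / tree_file / tree_newick)")
}

.cfg_classes <- function(config) {
  if (is.null(config$classes)) return(NULL)
  cl <- lapply(seq_len(NROW(config$classes)), function(i) {
    x <- if (is.data.frame(config$classes)) as.list(config$classes[i, ])
         else config$classes[[i]]
    list(class = x$class, taxa = unlist(x$taxa))
  })
  branch_class_spec(cl, default = config$default_class %||% "alpha")
}

.mk_report <- function(pipeline, seed, stages) {
  structure(list(pipeline = pipeline, seed = seed,
                 version = as.character(utils::packageVersion("paralogsel")),
                 stages = stages), class = "run_report")
}

#' Run the trait pipeline: traits -> ML + LRT -> MCMC -> stepping stone -> BFs
#'
#' Stages: trait assignment from an MSA (when given) or a trait table;
#' branch tagging; ML fits of the independent and dependent models with the
#' nested LRT; MCMC on the dependent model, unconstrained and with each
#' configured ancestral node fossilized to both states; stepping-stone log
#' marginal likelihoods and the log-Bayes-factor table.
#'
#' @param config List or JSON path. Recognized keys: `tree`/`tree_file`/
#'   `tree_newick`; `traits` (trait_table) or `trait_csv` or `msa_fasta` +
#'   `site` (list: ref_id, position, residue, window); `classes` (list of
#'   `{class, taxa}`) + `default_class`; `constraints` (list of
#'   `{taxa}` node selectors, each scanned in both states); `mcmc` and
#'   `ss` (overrides for [mcmc_config()]/[ss_config()]); `seed`;
#'   `outdir` (optional; report JSON and MCMC sample CSVs are written there).
#' @return A `run_report`.
#' @export
run_trait_pipeline <- function(config) {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  tree <- .cfg_tree(config)
  stages <- list()

  if (!is.null(config$traits)) {
    traits <- config$traits
  } else if (!is.null(config$trait_csv)) {
    traits <- read_trait_csv(config$trait_csv)
  } else if (!is.null(config$msa_fasta)) {
    msa <- read_protein_msa(config$msa_fasta)
    sd_ <- config$site
    site <- site_definition(sd_$ref_id, sd_$position,
                            sd_$residue %||% "D", sd_$window %||% 5L)
    traits <- assign_traits(msa, site)
  } else stop("config error: no traits / trait_csv / msa_fasta")
  stages$traits <- list(n = length(traits),
                        counts = table(unclass(traits)))

  spec <- .cfg_classes(config)
  if (!is.null(spec)) tree <- tag_branches(tree, spec)
  dependent <- !is.null(spec) &&
    any((tree$branch.class %||% "alpha") == "delta")

  set.seed(derive_seed(seed, "ml_indep"))
  m_ind <- trait_model(0.1, 0.1, root_prior = config$root_prior %||% "stationary")
  fit_ind <- fit_trait_ml(tree, traits, m_ind)
  fit_dep <- NULL
  if (dependent) {
    set.seed(derive_seed(seed, "ml_dep"))
    m_dep <- trait_model(0.1, 0.1, q10_delta = 0.1,
                         root_prior = config$root_prior %||% "stationary")
    fit_dep <- fit_trait_ml(tree, traits, m_dep,
                            init = c(fit_ind$estimates, fit_ind$estimates[2]))
    lrt <- lrt_dependent_vs_independent(fit_ind$loglik, fit_dep$loglik)
  } else lrt <- NULL
  stages$ml <- list(independent = fit_ind[c("estimates", "loglik")],
                    dependent = if (dependent)
                      fit_dep[c("estimates", "loglik")],
                    lrt = lrt)

  model <- if (dependent) fit_dep$model else fit_ind$model
  mcfg_over <- config$mcmc %||% list()
  sscfg_over <- config$ss %||% list()
  mk_mcfg <- function(stage) do.call(mcmc_config,
    utils::modifyList(list(seed = derive_seed(seed, stage)), mcfg_over))
  mk_sscfg <- function(stage) do.call(ss_config,
    utils::modifyList(list(seed = derive_seed(seed, stage)), sscfg_over))

  runs <- list(unconstrained = list())
  for (i in seq_along(config$constraints %||% list())) {
    taxa <- unlist(config$constraints[[i]]$taxa)
    for (st in c("present", "absent"))
      runs[[paste0("node", i, "_", st)]] <-
        list(node_constraint(taxa, st))
  }
  mcmc_res <- list(); logml <- numeric(0)
  for (nm in names(runs)) {
    mc <- run_trait_mcmc(tree, traits, model, runs[[nm]],
                         mk_mcfg(paste0("mcmc_", nm)))
    ssr <- stepping_stone_logml(tree, traits, model, runs[[nm]],
                                mk_sscfg(paste0("ss_", nm)))
    mcmc_res[[nm]] <- list(medians = mc$medians,
                           ratio_medians = mc$ratio_medians,
                           acceptance = mc$diagnostics$acceptance,
                           samples = mc$samples)
    logml[nm] <- ssr$logml
  }
  bf <- list()
  for (nm in setdiff(names(logml), "unconstrained"))
    bf[[paste0(nm, "_vs_unconstrained")]] <-
      log_bayes_factor(logml[[nm]], logml[["unconstrained"]])
  for (i in seq_along(config$constraints %||% list())) {
    a <- paste0("node", i, "_present"); b <- paste0("node", i, "_absent")
    if (all(c(a, b) %in% names(logml)))
      bf[[paste0("node", i, "_present_vs_absent")]] <-
        log_bayes_factor(logml[[a]], logml[[b]])
  }
  stages$mcmc <- mcmc_res
  stages$logml <- as.list(logml)
  stages$bayes_factors <- bf

  report <- .mk_report("trait", seed, stages)
  .write_report(report, config$outdir)
  report
}

#' Run the selection pipeline: nuisance fit, per-partition FEL, Contrast-FEL
#'
#' @param config List or JSON path. Keys: tree input as in
#'   [run_trait_pipeline()]; `codon_fasta` or `aln` (a [codon_alignment()]);
#'   `partition_csv` (columns `id,partition`) or `partition` (named vector);
#'   `sites` (codon indices; default all) and `site_labels`;
#'   `reroot_tip` (optional); `outdir`.
#' @return A `run_report` whose `stages$table` mirrors the per-site summary:
#'   `site, dnds_alpha, p_alpha, dnds_delta, p_delta, p_contrast`.
#' @export
run_selection_pipeline <- function(config) {
  config <- read_config(config)
  stages <- list()
  if (!is.null(config$aln)) {
    aln <- config$aln
  } else {
    tree <- .cfg_tree(config)
    if (!is.null(config$reroot_tip)) tree <- reroot_on_tip(tree, config$reroot_tip)
    partition <- if (!is.null(config$partition_csv)) {
      d <- read.csv(config$partition_csv, stringsAsFactors = FALSE)
      setNames(d$partition, d$id)
    } else unlist(config$partition)
    aln <- read_codon_fasta(config$codon_fasta, tree, partition,
                            config$site_labels)
  }
  sites <- config$sites %||% seq_len(aln$n_site)
  nuis <- fit_global_nuisance(aln)
  stages$nuisance <- nuis[c("kappa", "omega", "scale", "loglik")]
  rows <- lapply(sites, function(s) {
    fa <- fel_site_test(aln, s, "alpha", nuis)
    fd <- fel_site_test(aln, s, "delta", nuis)
    ct <- contrast_fel_site_test(aln, s, nuis)
    data.frame(site = aln$site_labels[s],
               dnds_alpha = fa$dnds, p_alpha = fa$p_value,
               dnds_delta = fd$dnds, p_delta = fd$p_value,
               p_contrast = ct$p_value, contrast_ratio = ct$ratio,
               stringsAsFactors = FALSE)
  })
  stages$table <- do.call(rbind, rows)
  report <- .mk_report("selection", config$seed %||% 1L, stages)
  .write_report(report, config$outdir)
  if (!is.null(config$outdir))
    write.csv(stages$table, file.path(config$outdir, "site_table.csv"),
              row.names = FALSE)
  report
}

#' Run the physiology pipeline: per-trace SSI, group tests, expression calls
#'
#' @param config List or JSON path. Keys: `traces` (list of
#'   [current_trace()] objects, or of `{file, events}` CSV specs),
#'   `groups` (labels aligned with traces), `design`, `comparisons`;
#'   optionally `expression` (`counts`, `lengths`, `library_total`,
#'   `metric`, `threshold`, `gene_ids`); `outdir`.
#' @return A `run_report` with per-trace SSI, group statistics and the
#'   expression-call table; the report echoes the window parameters used.
#' @export
run_physiology <- function(config) {
  config <- read_config(config)
  stages <- list()
  if (!is.null(config$traces)) {
    traces <- lapply(config$traces, function(x) {
      if (inherits(x, "current_trace")) x
      else read_trace_csv(x$file, x$events)
    })
    ssi <- vapply(traces, function(tr) trace_ssi(tr)$ssi, numeric(1))
    stages$ssi <- data.frame(trace = seq_along(ssi),
                             group = config$groups %||% rep("all", length(ssi)),
                             ssi = ssi)
    stages$windows <- traces[[1]][c("peak_window", "ss_center",
                                    "ss_halfwidth", "amil_equilibration",
                                    "amil_window")]
    if (!is.null(config$groups) && length(unique(config$groups)) > 1)
      stages$group_test <- compare_groups(ssi, config$groups,
                                          design = config$design %||% "two-sample",
                                          comparisons = config$comparisons)
  }
  if (!is.null(config$expression)) {
    e <- config$expression
    stages$expression <- expression_call(e$counts, e$lengths,
                                         e$library_total,
                                         metric = e$metric %||% "RPKM",
                                         threshold = e$threshold %||% 0.3,
                                         gene_ids = e$gene_ids)
  }
  report <- .mk_report("physiology", config$seed %||% 1L, stages)
  .write_report(report, config$outdir)
  report
}

.write_report <- function(report, outdir) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.report_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

# strip bulky sample frames from the JSON view (they go to CSV instead)
.report_json <- function(report) {
  r <- unclass(report)
  for (nm in names(r$stages$mcmc))
    r$stages$mcmc[[nm]]$samples <- NULL
  r
}
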