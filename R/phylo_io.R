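# Tree I/O, MRCA queries and branch-class tagging. Trees are ape "phylo"
# objects; branch classes live in tree$branch.class, a character vector
# aligned with the rows of tree$edge.

#' Read a rooted phylogeny from newick text or a file
#'
#' Accepts quoted labels and square-bracket comments (stripped), polytomies
#' and zero-length branches. Internal node labels are preserved but unused.
#'
#' @param text Newick string (exactly one of `text`/`file`).
#' @param file Path to a newick file.
#' @return An ape `phylo` object with branch lengths.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text)  # strip comments
  .check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("newick parse error: unreadable tree string")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("non-finite branch length")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  tree
}

# cheap bracket-balance scan so parse errors carry a character offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at character ", i, ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("newick parse error at character ", nchar(text),
         ": ", depth, " unclosed '('")
  if (!grepl(";", text))
    stop("newick parse error at character ", nchar(text), ": missing ';'")
  invisible(TRUE)
}

#' Write a phylogeny as a newick string or file
#'
#' @param tree `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @param digits Branch-length precision.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Most recent common ancestor of a taxon set
#'
#' Returns the node id (ape numbering) of the deepest node whose descendant
#' tip set contains `taxa`; a single taxon returns that tip's id.
#'
#' @param tree `phylo` object.
#' @param taxa Character vector of tip labels.
#' @export
mrca_node <- function(tree, taxa) {
  taxa <- unique(taxa)
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad)) stop("unknown taxon: ", paste(bad, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  if (setequal(taxa, tree$tip.label)) return(ape::Ntip(tree) + 1L)
  ape::getMRCA(tree, taxa)
}

#' Branch-class specification
#'
#' A list of named clades (each a taxon set); branches whose descendant tips
#' all fall inside a clade's taxon set get that clade's class, everything
#' else the default class.
#'
#' @param classes List of `list(class = <name>, taxa = <character vector>)`.
#' @param default Class name for untagged branches.
#' @export
branch_class_spec <- function(classes = list(), default = "alpha") {
  nm <- vapply(classes, function(x) x$class, character(1))
  if (anyDuplicated(nm)) stop("class names must be unique")
  if (default %in% nm) stop("default class name collides with a clade class")
  structure(list(classes = classes, default = default),
            class = "branch_class_spec")
}

# descendant tip-label sets for every node, postorder accumulation
.node_tip_sets <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nn)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Tag branches with class labels from clade definitions
#'
#' A branch gets class `c` iff every tip below it belongs to `c`'s taxon set
#' (so a clade's stem branch is included); other branches get the default
#' class. When taxon sets overlap so that a branch is eligible for more than
#' one class, later entries override earlier ones (`on_overlap = "override"`,
#' the default) or an error naming the branch is raised
#' (`on_overlap = "error"`).
#'
#' @param tree `phylo` object.
#' @param spec A [branch_class_spec()].
#' @param on_overlap `"override"` or `"error"`.
#' @return The tree with `tree$branch.class` set (length `nrow(tree$edge)`).
#' @export
tag_branches <- function(tree, spec, on_overlap = c("override", "error")) {
  on_overlap <- match.arg(on_overlap)
  stopifnot(inherits(spec, "branch_class_spec"))
  for (cl in spec$classes) {
    bad <- setdiff(cl$taxa, tree$tip.label)
    if (length(bad))
      stop("class '", cl$class, "' names unknown taxa: ",
           paste(bad, collapse = ", "))
  }
  sets <- .node_tip_sets(tree)
  ne <- nrow(tree$edge)
  cls <- rep(spec$default, ne)
  for (cl in spec$classes) {
    for (i in seq_len(ne)) {
      below <- sets[[tree$edge[i, 2]]]
      if (all(below %in% cl$taxa)) {
        if (cls[i] != spec$default && cls[i] != cl$class &&
            on_overlap == "error")
          stop("branch to node ", tree$edge[i, 2],
               " eligible for classes '", cls[i], "' and '", cl$class, "'")
        cls[i] <- cl$class
      }
    }
  }
  tree$branch.class <- cls
  tree
}

#' Reroot a tree on a tip
#'
#' @param tree `phylo` object.
#' @param tip Tip label to use as outgroup.
#' @export
reroot_on_tip <- function(tree, tip) {
  if (!tip %in% tree$tip.label) stop("unknown taxon: ", tip)
  ape::root(tree, outgroup = tip, resolve.root = TRUE)
}

# ---- trait tables -----------------------------------------------------------

#' Construct a taxon -> trait-state table
#'
#' States are `"absent"`, `"present"` or `"unknown"` (CSV tokens `0`, `1`,
#' `unknown`).
#'
#' @param taxa Character vector of taxon names (unique).
#' @param states Character vector of states, recycled checks not applied.
#' @export
trait_table <- function(taxa, states) {
  if (anyDuplicated(taxa)) stop("duplicate taxa in trait table")
  states <- as.character(states)
  states[states == "0"] <- "absent"
  states[states == "1"] <- "present"
  bad <- setdiff(unique(states), c("absent", "present", "unknown"))
  if (length(bad)) stop("invalid trait state(s): ", paste(bad, collapse = ", "))
  structure(setNames(states, taxa), class = "trait_table")
}

#' @rdname trait_table
#' @param path CSV with columns `taxon,state`, state in `{0,1,unknown}`.
#' @export
read_trait_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(d)))
    stop("trait CSV needs columns taxon,state")
  trait_table(d$taxon, d$state)
}

#' @rdname trait_table
#' @param traits A `trait_table`.
#' @param file Output CSV path.
#' @export
write_trait_csv <- function(traits, file) {
  st <- unclass(traits)
  tok <- c(absent = "0", present = "1", unknown = "unknown")[st]
  write.csv(data.frame(taxon = names(st), state = unname(tok)),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# every tree tip must appear exactly once in the table (no silent defaults)
.validate_traits <- function(tree, traits) {
  stopifnot(inherits(traits, "trait_table"))
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss))
    stop("tips missing from trait table (add explicit 'unknown' rows): ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}

# ---- internal: postorder arrays handed to the C++ kernels -------------------

# Returns edges in postorder plus class indices (integer, 1-based into
# `levels`). Trees without branch.class get a single class.
.tree_arrays <- function(tree, class_levels = NULL) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  cls <- tree$branch.class
  if (is.null(cls)) cls <- rep("alpha", nrow(tree$edge))
  if (is.null(class_levels)) class_levels <- unique(cls)
  icls <- match(cls, class_levels)
  if (anyNA(icls)) stop("branch class not resolvable to a rate pair: ",
                        paste(setdiff(cls, class_levels), collapse = ", "))
  ord <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(eparent = tree$edge[ord, 1], echild = tree$edge[ord, 2],
       elen = tree$edge.length[ord], eclass = icls[ord],
       n_tip = nt, n_node = nn, root = nt + 1L,
       class_levels = class_levels, edge_order = ord)
}
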