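#' Rescaled node height within a language clade
#'
#' Node heights inside a clade are derived from classification levels: a
#' node housing languages sampled at level `L_s` of a clade whose deepest
#' classification level is `L_c` sits at `(L_c - L_s) * C` in raw units,
#' where `C` is the clade's relative age (height of the clade ancestor
#' relative to the root).  Raw units are made commensurable across clades
#' by dividing by `L_c`, so the clade ancestor (level 0) sits at height `C`
#' and tip-level nodes (level `L_c`) at 0, on a tree whose root has
#' height 1.
#'
#' @param L_c integer, maximum classification level in the clade (>= 1).
#' @param L_s integer, classification level of the node (0 = clade root).
#' @param C clade height relative to the root, in (0, 1].
#' @return dimensionless node height in `[0, C]`, monotone decreasing in
#'   `L_s`.
#' @export
#' @examples
#' rescale_node_height(4, 1, 0.5)  # 0.375
#' rescale_node_height(10, 7, 0.2) # 0.06
rescale_node_height <- function(L_c, L_s, C) {
  if (any(C <= 0)) stop("invalid clade: relative height C must be > 0")
  if (any(C > 1)) stop("invalid clade: relative height C must be <= 1")
  if (any(L_c < 1)) stop("invalid clade: max level L_c must be >= 1")
  if (any(L_s > L_c)) {
    stop("invalid taxonomy: sample level L_s exceeds clade max level L_c")
  }
  if (any(L_s < 0)) stop("invalid taxonomy: sample level L_s must be >= 0")
  (L_c - L_s) * C / L_c
}

# validate a taxonomy data.frame + clade data.frame pair; returns the
# taxonomy with a list-column `.path` of split classification paths
.validate_taxonomy <- function(taxonomy, clades) {
  need_t <- c("tip_id", "clade_id", "path", "sample_level")
  if (!all(need_t %in% names(taxonomy))) {
    stop("taxonomy table must have columns: ", paste(need_t, collapse = ", "))
  }
  need_c <- c("clade_id", "relative_height", "max_level")
  if (!all(need_c %in% names(clades))) {
    stop("clade table must have columns: ", paste(need_c, collapse = ", "))
  }
  if (anyDuplicated(taxonomy$tip_id)) {
    dup <- unique(taxonomy$tip_id[duplicated(taxonomy$tip_id)])
    stop("duplicate tip_id in taxonomy: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(clades$clade_id)) stop("duplicate clade_id in clade table")
  unknown <- setdiff(taxonomy$clade_id, clades$clade_id)
  if (length(unknown)) {
    stop("tips reference unknown clade(s): ", paste(unknown, collapse = ", "))
  }
  idx <- match(taxonomy$clade_id, clades$clade_id)
  C <- clades$relative_height[idx]
  L_c <- clades$max_level[idx]
  if (any(clades$relative_height <= 0) || any(clades$relative_height > 1)) {
    stop("invalid clade: relative_height must lie in (0, 1]")
  }
  if (any(clades$max_level < 1)) stop("invalid clade: max_level must be >= 1")
  paths <- strsplit(as.character(taxonomy$path), "|", fixed = TRUE)
  if (any(lengths(paths) < 1)) stop("invalid taxonomy: empty path")
  if (any(taxonomy$sample_level != lengths(paths))) {
    stop("invalid taxonomy: sample_level must equal the path depth")
  }
  if (any(taxonomy$sample_level > L_c)) {
    stop("invalid taxonomy: sample level L_s exceeds clade max level L_c")
  }
  taxonomy$.path <- paths
  taxonomy
}

# Recursively render the prefix tree of classification paths as a Newick
# fragment.  `tips` carries tip_id and `.path` (labels still to consume);
# the current node sits at classification `level` with height
# rescale_node_height(L_c, level, C).  Returns list(fragment, height);
# unary nodes are suppressed.  Tips whose paths are identical attach
# through a tie node at C/(2*L_c) so no two tips coincide exactly
# (identical tips would make the similarity matrix rank-deficient).
.prefix_newick <- function(tips, level, L_c, C) {
  h_here <- rescale_node_height(L_c, level, C)
  h_tie <- C / (2 * L_c)
  done <- lengths(tips$.path) == 0
  enders <- tips[done, , drop = FALSE]
  children <- list() # each: list(fragment, height)
  if (nrow(enders) == 1L) {
    children[[length(children) + 1L]] <- list(fragment = enders$tip_id, height = 0)
  } else if (nrow(enders) > 1L) {
    inner <- paste(sprintf("%s:%.12g", enders$tip_id, h_tie), collapse = ",")
    tie <- list(fragment = sprintf("(%s)", inner), height = h_tie)
    if (h_here <= h_tie) {
      # path-end node at (or below) the tie height: the tie node stands in
      # for this node entirely (deepest levels cannot have further children)
      return(tie)
    }
    children[[length(children) + 1L]] <- tie
  }
  rest <- tips[!done, , drop = FALSE]
  if (nrow(rest) > 0) {
    first <- vapply(rest$.path, `[`, character(1), 1L)
    for (lab in unique(first)) {
      grp <- rest[first == lab, , drop = FALSE]
      grp$.path <- lapply(grp$.path, `[`, -1L)
      children[[length(children) + 1L]] <-
        .prefix_newick(grp, level + 1L, L_c, C)
    }
  }
  if (length(children) == 1L) {
    return(children[[1L]]) # suppress unary node
  }
  frag <- paste(vapply(children, function(ch) {
    sprintf("%s:%.12g", ch$fragment, h_here - ch$height)
  }, character(1)), collapse = ",")
  list(fragment = sprintf("(%s)", frag), height = h_here)
}

#' Build the ultrametric cultural hierarchy from a language taxonomy
#'
#' Constructs a rooted, ultrametric tree over societies.  Within each
#' clade the classification paths form a prefix tree whose node heights
#' follow [rescale_node_height()]; each clade ancestor sits at its
#' relative age `C`, and all clades join a single root at height 1 (no
#' between-clade structure is assumed).  Multifurcations are preserved;
#' unary nodes are suppressed.  Tips with identical full classification
#' paths attach to a common parent at `C / (2 L_c)` above zero so the
#' similarity matrix stays nonsingular.
#'
#' @param taxonomy data.frame with columns `tip_id`, `clade_id`, `path`
#'   (pipe-delimited classification labels, clade root to tip) and
#'   `sample_level` (must equal the path depth); a `language_code` column
#'   is carried but unused.
#' @param clades data.frame with columns `clade_id`, `relative_height`
#'   (`C`, in (0,1]), `max_level` (`L_c`) and optionally `n_languages`.
#' @return an [ape::phylo] tree; root height 1, all tips at height 0.
#' @export
build_hierarchy <- function(taxonomy, clades) {
  taxonomy <- .validate_taxonomy(taxonomy, clades)
  clade_frags <- character(0)
  for (cid in unique(taxonomy$clade_id)) {
    sub <- taxonomy[taxonomy$clade_id == cid, , drop = FALSE]
    crow <- clades[clades$clade_id == cid, , drop = FALSE]
    C <- crow$relative_height[1]
    L_c <- crow$max_level[1]
    if (nrow(sub) == 1L) {
      warning("clade '", cid, "' has a single tip; degenerate branch to root")
      clade_frags <- c(clade_frags, sprintf("%s:1", sub$tip_id))
      next
    }
    node <- .prefix_newick(sub, 0L, L_c, C)
    clade_frags <- c(clade_frags,
                     sprintf("%s:%.12g", node$fragment, 1 - node$height))
  }
  if (length(clade_frags) == 1L && !grepl("^\\(", clade_frags[1L])) {
    stop("taxonomy must contain at least two tips")
  }
  nwk <- sprintf("(%s);", paste(clade_frags, collapse = ","))
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree)) stop("internal error: failed to assemble tree")
  tree
}

#' Phylogenetic similarity matrix from a cultural hierarchy
#'
#' Similarity between two societies is the fraction of the root-to-tip
#' path they share: `P_ij = 1 - height(MRCA(i, j))` on a tree with root
#' height 1, i.e. the Brownian-motion correlation the tree implies.
#' Computed via [ape::vcv.phylo()] scaled by the tree depth.
#'
#' @param tree an ultrametric [ape::phylo] with root height 1 (as produced
#'   by [build_hierarchy()]); other depths are rescaled to 1.
#' @param tol ultrametricity tolerance.
#' @return symmetric matrix with unit diagonal, entries in `[0, 1]`,
#'   dimnames = tip labels.  Entries are 0 exactly for pairs whose MRCA is
#'   the root.
#' @export
phylo_similarity <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.ultrametric(tree, tol = max(tol, 1e-8))) {
    stop("tree is not ultrametric")
  }
  V <- ape::vcv.phylo(tree)
  depth <- max(diag(V))
  P <- V / depth
  diag(P) <- 1
  P <- (P + t(P)) / 2
  if (nrow(P) > 1 && min(P[upper.tri(P)]) >= 0.5) {
    warning("every pair of societies shares at least half its history: ",
            "the similarity matrix carries little contrast and is close ",
            "to non-identifiable downstream")
  }
  P
}
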