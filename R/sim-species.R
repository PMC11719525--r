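#' Simulate species gene sets descending from a planted tree
#'
#' An ancestral pool of 5UC-cassette-containing genes evolves down the
#' planted species tree; on every branch each surviving gene is lost
#' independently with probability `loss_rate`. Leaves inherit the surviving
#' sets and ortholog maps are identity on shared ancestral genes, so the
#' ortholog-sharing distance reflects path length in the planted tree.
#'
#' @param config a [sim_config] (uses `tree`, `loss_rate`, `pool_size`,
#'   `seed`).
#' @return list: `sets` (named list of per-species gene ids), `orthologs`
#'   (identity ortholog data.frame for all ordered pairs), `tree` (planted
#'   Newick string).
#' @export
simulate_species_sets <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, "species"))
  phy <- ape::read.tree(text = config$tree)
  if (is.null(phy) || length(phy$tip.label) < 3) {
    stopf("planted tree needs >= 3 leaves")
  }
  pool <- sprintf("ANC%04d", seq_len(config$pool_size))
  n_node <- max(phy$edge)
  node_sets <- vector("list", n_node)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  node_sets[[root]] <- pool
  # per-branch survival: (1 - loss_rate)^branch_length when the planted
  # tree carries (clock-like) branch lengths, else loss_rate per branch
  elen <- phy$edge.length %||% rep(1, nrow(phy$edge))
  p_surv <- (1 - config$loss_rate)^elen
  # process edges parent-first regardless of how ape ordered them
  done <- rep(FALSE, nrow(phy$edge))
  assigned <- rep(FALSE, n_node); assigned[root] <- TRUE
  while (!all(done)) {
    ready <- which(!done & assigned[phy$edge[, 1]])
    for (e in ready) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      src <- node_sets[[parent]]
      keep <- runif(length(src)) < p_surv[e]
      node_sets[[child]] <- src[keep]
      assigned[child] <- TRUE; done[e] <- TRUE
    }
  }
  sets <- setNames(node_sets[seq_along(phy$tip.label)], phy$tip.label)

  sp <- names(sets)
  ortho <- data.table::rbindlist(lapply(sp, function(a)
    data.table::rbindlist(lapply(setdiff(sp, a), function(b) {
      shared <- intersect(sets[[a]], sets[[b]])
      if (!length(shared)) return(NULL)
      data.table::data.table(species_a = a, gene_a = shared,
                             species_b = b, gene_b = shared)
    }))))
  list(sets = sets, orthologs = as.data.frame(ortho),
       tree = config$tree)
}

#' Write an ortholog table as TSV
#'
#' @param orthologs data.frame `species_a`, `gene_a`, `species_b`, `gene_b`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  utils::write.table(orthologs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
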