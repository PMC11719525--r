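# Cross-species counting of 5UC cassette exons and ortholog-sharing
# clustering of the genes that carry them.

#' Per-species summary of 5UC cassette exons
#'
#' Runs the classifier and event generation on one species' annotation and
#' returns a summary row: protein-coding genes, transcript isoforms, unique
#' exons, alternative (non-constitutive) internal exons, and the genes /
#' isoforms / exon counts of the 5UC cassette subset.
#'
#' @param models a [gene_models] object (or a GTF path, read via
#'   [read_gtf()]).
#' @param species label for the output row.
#' @return one-row data.frame.
#' @export
species_5uc_stats <- function(models, species = "species") {
  if (is.character(models)) models <- read_gtf(models)
  if (!nrow(models$cds)) stopf("annotation has no CDS features")
  cls <- classify_all(models)
  ex <- models$exons
  n_exons <- nrow(unique(ex[, c("gene_id", "chrom", "start", "end",
                                "strand")]))
  alt <- sum(cls$exons$splice_class != "CONSTITUTIVE")
  g5 <- fiveuc_ase_genes(cls$exons)
  tr5 <- sum(models$transcripts$gene_id %in% g5)
  data.frame(
    species = species,
    genes = nrow(models$genes),
    transcripts = nrow(models$transcripts),
    exons = n_exons,
    alternative_exons = alt,
    fiveuc_ase_genes = length(g5),
    fiveuc_ase_transcripts = tr5,
    fiveuc_ases = sum(cls$exons$coding_type == "TYPE2_5UC" &
                        cls$exons$splice_class == "ASE"),
    stringsAsFactors = FALSE)
}

#' Ortholog-sharing distance between species gene sets
#'
#' `shared(A, B)` counts genes in A's set with at least one ortholog in B's
#' set; the two directions are symmetrised by their mean and turned into a
#' Jaccard-style distance
#' `d = 1 - shared / (|A| + |B| - shared)`, bounded in `[0, 1]` with zero
#' diagonal.
#'
#' @param sets named list of per-species gene-id vectors (e.g. 5UC-ASE
#'   genes).
#' @param orthologs data.frame with columns `species_a`, `gene_a`,
#'   `species_b`, `gene_b` covering every ordered species pair (identity
#'   maps may simply list the shared gene ids).
#' @return symmetric distance matrix with a `shared` attribute holding the
#'   symmetrised shared counts.
#' @export
sharing_distance <- function(sets, orthologs) {
  sp <- names(sets)
  if (is.null(sp) || length(sp) < 2) stopf("need >= 2 named species sets")
  od <- data.table::as.data.table(orthologs)
  need <- setdiff(sp, unique(c(od$species_a, od$species_b)))
  if (length(need)) stopf("species absent from ortholog maps: %s",
                          paste(need, collapse = ", "))
  k <- length(sp)
  shared_dir <- matrix(0, k, k, dimnames = list(sp, sp))
  for (a in sp) for (b in sp) {
    if (a == b) { shared_dir[a, b] <- length(sets[[a]]); next }
    m <- od[species_a == a & species_b == b & gene_a %in% sets[[a]] &
              gene_b %in% sets[[b]]]
    shared_dir[a, b] <- length(unique(m$gene_a))
  }
  sym <- (shared_dir + t(shared_dir)) / 2
  sizes <- lengths(sets)
  d <- matrix(0, k, k, dimnames = list(sp, sp))
  for (a in sp) for (b in sp) {
    if (a == b) next
    s <- sym[a, b]
    d[a, b] <- 1 - s / (sizes[a] + sizes[b] - s)
  }
  attr(d, "shared") <- sym
  d
}

#' Ward clustering of a species distance matrix
#'
#' Agglomerative minimum-variance (Ward) clustering on the squared-distance
#' convention, with a Newick export whose node heights are the merge
#' heights. Merge heights are guaranteed non-decreasing.
#'
#' @param dist_matrix symmetric non-negative matrix, zero diagonal.
#' @return list: `hclust` (the tree), `merges` (data.frame of heights),
#'   `newick` (string).
#' @export
ward_cluster <- function(dist_matrix) {
  m <- as.matrix(dist_matrix)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stopf("distance matrix must be symmetric")
  }
  if (nrow(m) < 2) stopf("need >= 2 leaves")
  hc <- stats::hclust(stats::as.dist(m), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  list(
    hclust = hc,
    merges = data.frame(step = seq_along(hc$height), height = hc$height),
    newick = ape::write.tree(phy))
}
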