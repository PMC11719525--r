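#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. All randomness in
#' the generator flows from `seed`; each emitted artifact uses its own
#' labelled stream derived from it, so adding artifacts never perturbs
#' existing ones.
#'
#' @param seed master integer seed.
#' @param quotas named integer vector of genes to plant per
#'   `"<coding_type>:<splice_class>"` cell (e.g. `"TYPE2_5UC:ASE" = 10`);
#'   the default plants 10 genes in each of the 20 cells.
#' @param type_median_length named numeric, target median exon length (nt)
#'   per coding type for the planted internal exon; the 5UC class is drawn
#'   larger than the others, mirroring the observed length shift.
#' @param length_sdlog log-normal spread of exon lengths.
#' @param intron_length intron size (nt); must exceed the coverage window.
#' @param n_tissues number of tissues; the first three are "divergent"
#'   tissues (brain/muscle/testis-like) with a larger tissue effect.
#' @param tissue_tau_divergent,tissue_tau_other s.d. of the per-(event,
#'   tissue) shift added to the true inclusion level.
#' @param samples_per_tissue samples simulated per tissue.
#' @param depth mean junction read budget per event and sample.
#' @param psi_moderate_frac fraction of events planted at moderate inclusion
#'   (0.3 < psi < 0.75); the rest sit near 0 or 1, giving the bimodal
#'   inclusion landscape seen in real tissue panels.
#' @param bound_fraction fraction of 5UC cassette exons bound by the
#'   simulated RBP.
#' @param fold coverage fold-enrichment over background in the bound window.
#' @param enrich_width width (nt) of the upstream bound window.
#' @param lambda_bg background coverage intensity per bin.
#' @param cov_bin_size coverage track bin size (nt).
#' @param kd_effect inclusion change of bound events upon RBP knockdown.
#' @param kd_down_fraction fraction of unbound events given the opposite
#'   inclusion change (indirect knockdown responders), populating the DOWN
#'   delta-PSI group without upstream binding.
#' @param tpm_sdlog log-normal noise on simulated TPMs.
#' @param base_tpm total expression per event (TPM).
#' @param tree Newick string of the planted species tree.
#' @param loss_rate per-branch probability that an ancestral gene is lost.
#' @param pool_size ancestral 5UC-ASE gene pool size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       quotas = default_quotas(),
                       type_median_length = c(
                         TYPE1_5UTR = 122, TYPE2_5UC = 161, TYPE3_CDS = 122,
                         TYPE4_C3U = 122, TYPE5_3UTR = 122),
                       length_sdlog = 0.35,
                       intron_length = 1000L,
                       n_tissues = 30L,
                       tissue_tau_divergent = 0.15,
                       tissue_tau_other = 0.02,
                       samples_per_tissue = 5L,
                       depth = 200,
                       psi_moderate_frac = 0.15,
                       bound_fraction = 0.5,
                       fold = 2,
                       enrich_width = 500L,
                       lambda_bg = 5,
                       cov_bin_size = 10L,
                       kd_effect = 0.3,
                       kd_down_fraction = 0.1,
                       tpm_sdlog = 0.05,
                       base_tpm = 20,
                       tree = default_species_tree(),
                       loss_rate = 0.15,
                       pool_size = 300L) {
  stopifnot(all(quotas >= 0), fold >= 1, intron_length >= 600,
            abs(kd_effect) <= 1, psi_moderate_frac >= 0,
            psi_moderate_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_quotas <- function() {
  cells <- as.vector(outer(CODING_TYPES,
                           c("ASE", "SSE", "OTHER_ALT", "CONSTITUTIVE"),
                           paste, sep = ":"))
  setNames(rep(10L, length(cells)), cells)
}

#' @rdname sim_config
#' @export
balanced_species_tree <- function() {
  # fully balanced 8-leaf ultrametric tree (depth 6). Minimum-variance
  # clustering penalises attaching a singleton outgroup to a large clade,
  # so ladder-like topologies are not representable by a Ward dendrogram
  # even from exact distances; topology-recovery properties are therefore
  # evaluated on balanced planted trees.
  paste0("(((s1:1,s2:1):2,(s3:1,s4:1):2):3,",
         "((s5:1,s6:1):2,(s7:1,s8:1):2):3);")
}

#' @rdname sim_config
#' @export
default_species_tree <- function() {
  # ultrametric (all leaves at depth 6): with per-branch survival
  # (1 - loss_rate)^length, ortholog sharing decays with divergence time,
  # as it would under a molecular clock
  paste0("((((((human:0.6,macaque:0.6):0.9,(mouse:0.9,rat:0.9):0.6):0.9,",
         "cow:2.4):0.9,chicken:3.3):0.9,frog:4.2):1.8,",
         "((zebrafish:2.1,medaka:2.1):1.5,shark:3.6):2.4);")
}
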