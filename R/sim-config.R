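#' Simulation configuration for a 3'-end sequencing stability experiment
#'
#' Builds the configuration object consumed by [simulate_annotation()],
#' [simulate_kinetics()] and [simulate_dataset()]. The defaults emulate the
#' design of a metabolic-labeling 3'-end sequencing study: three conditions
#' ("cell lines"), three RNA fractions per condition (total, 4sU-labeled,
#' flow-through), two biological replicates, a 1-hour 4sU pulse, first-order
#' decay, genes carrying 1-3 poly(A) sites (PAS) in their 3'-most exon and
#' optionally one intronic PAS.
#'
#' Decay kinetics follow the steady-state labeling model: for synthesis rate
#' `s` (transcripts/h) and decay rate `k` (1/h), total abundance is `s/k`, the
#' labeled (newly made) pool after a pulse of `t` hours is `(s/k)(1-exp(-kt))`
#' and the unlabeled (pre-existing, flow-through) pool is `(s/k)exp(-kt)`.
#'
#' @param n_genes number of genes to simulate.
#' @param pas_per_gene named probability vector over `"1"`, `"2"`, `"3"` giving
#'   the distribution of the number of 3'-most-exon PASs per gene.
#' @param ipa_probability probability that a gene carries one intronic PAS.
#' @param autr_size_range numeric length-2; range (nt) of the distance between
#'   consecutive 3'-most-exon PASs (the alternative 3'UTR, aUTR).
#' @param halflife_meanlog,halflife_sdlog log-normal parameters of gene
#'   half-life in hours (default median 4 h, sdlog 0.8).
#' @param synthesis_meanlog,synthesis_sdlog log-normal parameters of gene
#'   synthesis rate (arbitrary transcripts/h units; only ratios matter).
#' @param labeling_time 4sU pulse duration in hours.
#' @param depth expected sequenced reads per sample.
#' @param conditions named list of condition specifications. Each element may
#'   contain `k_scale` (decay-rate multiplier), `frac_genes` (fraction of genes
#'   the multiplier applies to) and `dpas_k_scale` (multiplier applied to the
#'   decay rate of non-proximal 3'UTR isoforms in that condition only).
#' @param replicates biological replicates per condition.
#' @param dpas_k_factor decay-rate multiplier applied per step of distal rank
#'   within the 3'-most exon (distal isoforms less stable when > 1).
#' @param dpas_affected_frac fraction of multi-PAS genes to which
#'   `dpas_k_factor` applies; the rest keep equal isoform decay rates.
#' @param ipa_k_factor decay-rate multiplier of intronic-PAS (IPA) isoforms
#'   relative to the gene's terminal-exon rate.
#' @param ipa_intron_coupling exponent coupling the IPA decay multiplier to
#'   host-intron size (0 = uncoupled; > 0 makes IPA isoforms in larger introns
#'   less stable).
#' @param intron_size_range range (nt) of simulated intron sizes.
#' @param gene_type_probs named probability vector over gene types.
#' @param lncrna_halflife_scale half-life multiplier for lncRNA genes.
#' @param utr_gc_range range of per-gene GC content of the transcribed region.
#' @param read_length aligned genomic length of simulated reads (nt).
#' @param tail_range integer length-2; range of non-genomic poly(A)-tail Ts
#'   soft-clipped at the read 5' end (in read orientation).
#' @param microheterogeneity maximum random shift (nt) of a read 3' end around
#'   its true cleavage site.
#' @param decoy_fraction fraction of reads emitted as internal-priming-like
#'   decoys: random position/strand, 0-1 clipped Ts.
#' @param low_mapq_fraction fraction of reads drawn with mapping quality < 10.
#' @param contamination fractionation cross-contamination: fraction of the
#'   labeled pool observed in the flow-through fraction and vice versa.
#' @param seed integer seed anchoring all randomness of the generator.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 200,
                       pas_per_gene = c("1" = 0.5, "2" = 0.4, "3" = 0.1),
                       ipa_probability = 0.15,
                       autr_size_range = c(200, 2000),
                       halflife_meanlog = log(4),
                       halflife_sdlog = 0.8,
                       synthesis_meanlog = log(10),
                       synthesis_sdlog = 0.5,
                       labeling_time = 1,
                       depth = 5e4,
                       conditions = list(
                         cellA = list(),
                         cellB = list(),
                         cellC = list(k_scale = 2, frac_genes = 0.1)
                       ),
                       replicates = 2,
                       dpas_k_factor = 1.5,
                       dpas_affected_frac = 1,
                       ipa_k_factor = 3,
                       ipa_intron_coupling = 0,
                       intron_size_range = c(500, 5000),
                       gene_type_probs = c(mRNA = 0.85, lncRNA = 0.15),
                       lncrna_halflife_scale = 0.5,
                       utr_gc_range = c(0.3, 0.7),
                       read_length = 50,
                       tail_range = c(2, 3),
                       microheterogeneity = 0,
                       decoy_fraction = 0,
                       low_mapq_fraction = 0,
                       contamination = 0,
                       seed = 1) {
  stopifnot(n_genes >= 1, replicates >= 1, depth >= 0, labeling_time > 0,
            read_length >= 23)
  if (abs(sum(pas_per_gene) - 1) > 1e-8)
    stop("pas_per_gene probabilities must sum to 1")
  if (ipa_probability < 0 || ipa_probability > 1)
    stop("ipa_probability must lie in [0, 1]")
  if (decoy_fraction < 0 || decoy_fraction > 1)
    stop("decoy_fraction must lie in [0, 1]")
  if (contamination < 0 || contamination > 0.5)
    stop("contamination must lie in [0, 0.5]")
  if (autr_size_range[1] < 1 || autr_size_range[2] < autr_size_range[1])
    stop("invalid autr_size_range")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list")
  structure(
    list(n_genes = as.integer(n_genes),
         pas_per_gene = pas_per_gene,
         ipa_probability = ipa_probability,
         autr_size_range = autr_size_range,
         halflife_meanlog = halflife_meanlog,
         halflife_sdlog = halflife_sdlog,
         synthesis_meanlog = synthesis_meanlog,
         synthesis_sdlog = synthesis_sdlog,
         labeling_time = labeling_time,
         depth = depth,
         conditions = conditions,
         replicates = as.integer(replicates),
         dpas_k_factor = dpas_k_factor,
         dpas_affected_frac = dpas_affected_frac,
         ipa_k_factor = ipa_k_factor,
         ipa_intron_coupling = ipa_intron_coupling,
         intron_size_range = intron_size_range,
         gene_type_probs = gene_type_probs,
         lncrna_halflife_scale = lncrna_halflife_scale,
         utr_gc_range = utr_gc_range,
         read_length = as.integer(read_length),
         tail_range = as.integer(tail_range),
         microheterogeneity = as.integer(microheterogeneity),
         decoy_fraction = decoy_fraction,
         low_mapq_fraction = low_mapq_fraction,
         contamination = contamination,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes: %d | conditions: %s | replicates: %d\n",
              x$n_genes, paste(names(x$conditions), collapse = ", "),
              x$replicates))
  cat(sprintf("  depth/sample: %g | labeling time: %g h | seed: %d\n",
              x$depth, x$labeling_time, x$seed))
  cat(sprintf("  PAS/gene probs: %s | IPA prob: %g\n",
              paste(sprintf("%s:%g", names(x$pas_per_gene), x$pas_per_gene),
                    collapse = " "), x$ipa_probability))
  invisible(x)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `sample_id`, `condition`, `fraction`
#'   (one of `total`, `4sU`, `FT`) and `replicate`.
#' @export
sample_sheet <- function(config) {
  g <- expand.grid(replicate = seq_len(config$replicates),
                   fraction = c("total", "4sU", "FT"),
                   condition = names(config$conditions),
                   stringsAsFactors = FALSE)
  g <- g[, c("condition", "fraction", "replicate")]
  g$sample_id <- paste(g$condition, g$fraction, g$replicate, sep = "_")
  g[, c("sample_id", "condition", "fraction", "replicate")]
}
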