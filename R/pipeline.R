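# End-to-end pipeline on synthetic data: generate -> preprocess -> call
# stable nucleosomes -> build modification and motif feature matrices ->
# balanced forest evaluation + permutation importance -> satellite
# composition and occupancy. All randomness derives from the generator
# seed, so a fixed seed gives byte-identical outputs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Default co-localization map for the synthetic study
#'
#' Two heterochromatin-associated channels co-occur with the positive-class
#' nucleosomes; the remaining 35 channels are background-only.
#'
#' @return Named list usable as `coloc_map` in [synth_config()].
#' @export
default_coloc_map <- function() {
  list(H4K20me3 = list(class = "positive", intensity = 10),
       H3K9me3 = list(class = "positive", intensity = 6))
}

#' Run the full analysis pipeline on synthetic data
#'
#' @param cfg A [synth_config()]; its `coloc_map` defaults to
#'   [default_coloc_map()] if unset.
#' @param outdir Optional output directory; when given, all tables and a
#'   JSON evaluation summary are written there deterministically.
#' @param rf An [rf_config()]; the pipeline default uses 200 permutations
#'   per importance test to keep a full run in the minutes range.
#' @param partition_f Discovery fraction for motif elicitation.
#' @param max_mismatch Mismatch tolerance when matching motifs.
#' @param call_feature_marks Feature channels additionally run through the
#'   nucleosome caller for downstream composition/occupancy.
#' @return List with all intermediate and final results (invisibly when
#'   `outdir` is given).
#' @export
run_pipeline <- function(cfg = synth_config(),
                         outdir = NULL,
                         rf = rf_config(n_permutations = 200L,
                                        seed = cfg$seed),
                         partition_f = 0.2,
                         max_mismatch = 2L,
                         call_feature_marks = c("H4K20me3", "H3K4me3")) {
  if (is.null(cfg$coloc_map)) cfg$coloc_map <- default_coloc_map()
  ds <- synth_dataset(cfg)
  chrom_lengths <- vapply(ds$genome, nchar, integer(1))

  # pre-processing: dedup everything; depth-normalize the outcome samples
  pp_out <- preprocess_samples(ds$outcome_reads,
                               seed = derive_seed(cfg$seed, 11L))
  feat_dd <- lapply(ds$feature_reads, function(r) dedup_reads(r)$reads)
  feat_stats <- data.frame(
    sample = names(ds$feature_reads),
    n_total = vapply(ds$feature_reads, nrow, integer(1)),
    n_unique = vapply(feat_dd, nrow, integer(1)),
    stringsAsFactors = FALSE)
  feat_stats$duplicate_fraction <-
    ifelse(feat_stats$n_total > 0,
           1 - feat_stats$n_unique / feat_stats$n_total, 0)
  rownames(feat_stats) <- NULL

  # stable nucleosome calling for the outcome marks
  pos_mark <- unname(ds$marks["positive"])
  neg_mark <- unname(ds$marks["negative"])
  peaks <- lapply(pp_out$samples, call_nucleosomes,
                  chrom_lengths = chrom_lengths)
  peaks_by_class <- list(positive = peaks[[pos_mark]],
                         negative = peaks[[neg_mark]])

  # modification overlap features (deduplicated feature reads)
  mod_matrix <- build_modification_matrix(peaks_by_class, feat_dd)

  # 147 bp nucleosome-bound sequences, keyed like the matrix rows
  seq_for <- function(p, label) {
    if (nrow(p) == 0L) return(character(0))
    s <- vapply(seq_len(nrow(p)), function(i) {
      extract_sequence(ds$genome, p$chrom[i], p$start[i], p$end[i], "+")
    }, character(1))
    names(s) <- paste0(label, "_", p$chrom, "_", p$start)
    s
  }
  seqs_by_class <- list(positive = seq_for(peaks_by_class$positive, "positive"),
                        negative = seq_for(peaks_by_class$negative, "negative"))

  # motif features on the withheld classification partition
  part <- partition_sequences(seqs_by_class, f = partition_f,
                              seed = derive_seed(cfg$seed, 12L))
  motifs <- elicit_motifs(part$discovery)
  discovery_ids <- c(names(part$discovery$positive),
                     names(part$discovery$negative))
  motif_matrix <- build_motif_matrix(part$classification, motifs,
                                     max_mismatch = max_mismatch,
                                     discovery_ids = discovery_ids)

  # balanced forest evaluation on each matrix and their combination
  mod_eval <- run_balanced_evaluation(mod_matrix, rf)
  motif_eval <- run_balanced_evaluation(motif_matrix, rf)
  mod_sub <- mod_matrix[mod_matrix$id %in% motif_matrix$id, , drop = FALSE]
  combined <- combine_matrices(mod_sub, motif_matrix)
  combined_eval <- run_balanced_evaluation(combined, rf)

  # permutation significance of MDG importance
  bal_mod <- balance_downsample(mod_matrix,
                                seed = derive_seed(cfg$seed, 13L))
  mod_importance <- permutation_importance(bal_mod, rf)
  bal_motif <- balance_downsample(motif_matrix,
                                  seed = derive_seed(cfg$seed, 14L))
  motif_importance <- permutation_importance(bal_motif, rf)

  # downstream: TCCATT histograms, composition, occupancy
  hist_pos <- motif_occurrence_histogram(seqs_by_class$positive, "TCCATT")
  hist_neg <- motif_occurrence_histogram(seqs_by_class$negative, "TCCATT")

  feat_peaks <- list()
  for (mk in intersect(call_feature_marks, names(feat_dd))) {
    feat_peaks[[mk]] <- call_nucleosomes(feat_dd[[mk]],
                                         chrom_lengths = chrom_lengths)
  }
  peaks_by_mark <- c(stats::setNames(list(peaks[[pos_mark]],
                                          peaks[[neg_mark]]),
                                     c(pos_mark, neg_mark)),
                     feat_peaks)
  composition <- repeat_composition(peaks_by_mark, ds$repeats)

  fam_instances <- list(
    "satellite II" = ds$repeats[ds$repeats$rep_name == "HSATII", ,
                                drop = FALSE],
    "satellite III" = ds$repeats[ds$repeats$rep_name %in%
                                   c("(CATTC)n", "(GAATG)n"), ,
                                 drop = FALSE])
  occ_rows <- list()
  occ_profiles <- list()
  for (mk in names(peaks_by_mark)) {
    for (fam in names(fam_instances)) {
      inst <- fam_instances[[fam]]
      if (nrow(inst) == 0L) next
      prof <- occupancy_profile(peaks_by_mark[[mk]], inst)
      occ_profiles[[paste(mk, fam)]] <- prof
      occ_rows[[length(occ_rows) + 1L]] <-
        data.frame(mark = mk, family = fam, occupancy = prof$summary,
                   n_instances = prof$n_instances,
                   stringsAsFactors = FALSE)
    }
  }
  occupancy <- do.call(rbind, occ_rows)
  rownames(occupancy) <- NULL

  eval_summary <- function(ev, m) {
    list(accuracy_mean = ev$accuracy_mean, accuracy_sd = ev$accuracy_sd,
         auroc_mean = ev$auroc_mean, auroc_sd = ev$auroc_sd,
         n_rows = nrow(m), n_features = length(feature_columns(m)),
         n_repeats = ev$n_repeats)
  }
  results <- list(
    config = cfg,
    truth = ds$truth,
    repeats = ds$repeats,
    preprocess_stats = rbind(pp_out$stats[, names(feat_stats)], feat_stats),
    peaks_by_class = peaks_by_class,
    peaks_by_mark = peaks_by_mark,
    mod_matrix = mod_matrix,
    motifs = motifs,
    motif_matrix = motif_matrix,
    evaluations = list(modification = mod_eval, motif = motif_eval,
                       combined = combined_eval),
    importance = list(modification = mod_importance,
                      motif = motif_importance),
    tccatt = list(positive = hist_pos, negative = hist_neg),
    composition = composition,
    occupancy = occupancy,
    sequences = seqs_by_class)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(results$preprocess_stats,
              file.path(outdir, "preprocess_stats.tsv"))
    for (mk in names(peaks_by_mark)) {
      write_tsv(peaks_by_mark[[mk]],
                file.path(outdir, paste0("nucleosomes_",
                                         gsub("[^A-Za-z0-9._-]", "_", mk),
                                         ".tsv")))
    }
    write_tsv(mod_matrix, file.path(outdir, "modification_matrix.tsv"))
    write_tsv(motifs, file.path(outdir, "motifs.tsv"))
    write_tsv(motif_matrix, file.path(outdir, "motif_matrix.tsv"))
    write_tsv(mod_importance,
              file.path(outdir, "importance_modification.tsv"))
    write_tsv(motif_importance, file.path(outdir, "importance_motif.tsv"))
    write_tsv(composition, file.path(outdir, "composition.tsv"))
    write_tsv(occupancy, file.path(outdir, "occupancy.tsv"))
    hist_tab <- rbind(cbind(class = "positive", hist_pos$histogram),
                      cbind(class = "negative", hist_neg$histogram))
    write_tsv(hist_tab, file.path(outdir, "tccatt_histogram.tsv"))
    jsonlite::write_json(
      list(modification = eval_summary(mod_eval, mod_matrix),
           motif = eval_summary(motif_eval, motif_matrix),
           combined = eval_summary(combined_eval, combined),
           tccatt = list(
             fraction_positive = hist_pos$fraction_present,
             fraction_negative = hist_neg$fraction_present,
             max_positive = hist_pos$max_count,
             max_negative = hist_neg$max_count,
             median_positive = hist_pos$median_count)),
      file.path(outdir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(results))
  }
  results
}
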