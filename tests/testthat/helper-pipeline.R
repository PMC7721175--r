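# One full pipeline pass on a simulated dataset: simulate -> parse/merge ->
# compare -> requantify -> GEM-count -> annotate -> train -> predict ->
# combined filter.  Used by the end-to-end acceptance criterion.

run_end_to_end <- function(seed, genome_length = 1e6, n_chromosomes = 4,
                           decoys_per_tech = 20, dropout = 0.15,
                           use_vcf_roundtrip = FALSE) {
  cfg <- sim_config(genome_length = genome_length,
                    n_chromosomes = n_chromosomes, seed = seed)
  g <- generate_genome(cfg)
  imp <- implant_svs(g, cfg)
  ref <- Biostrings::DNAStringSet(g)
  cs <- make_labelled_callset(imp$truth, cfg, nchar(g),
                              decoys = decoys_per_tech,
                              dropout = c(SR = dropout, LR = dropout))
  sr_calls <- cs$sr; lr_calls <- cs$lr
  if (use_vcf_roundtrip) {
    fsr <- tempfile(fileext = ".vcf"); flr <- tempfile(fileext = ".vcf")
    write_sv_vcf(sr_calls, fsr, contigs = nchar(g))
    write_sv_vcf(lr_calls, flr, contigs = nchar(g))
    rt_sr <- parse_sv_vcf(fsr, "simA", "SR")
    rt_lr <- parse_sv_vcf(flr, "simA", "LR")
    ## ids/coords survive the round trip; caller column is per-file here
    sr_calls$pos1 <- rt_sr$pos1[match(sr_calls$id, rt_sr$id)]
    unlink(c(fsr, flr))
  }
  msr <- merge_calls(sr_calls); mlr <- merge_calls(lr_calls)
  cmp <- compare_technologies(msr, mlr)
  ## reads
  sr <- simulate_sr_reads(imp$alt, cfg, imp$blocks)
  lr <- simulate_lr_reads(imp$alt, cfg, imp$blocks)
  rdb <- debarcoded_reads(lr$reads)
  rq_sr <- requantify_svs(msr, ref, sr$reads, "SR")
  rq_lr <- requantify_svs(mlr, ref, rdb, "LR")
  pairs <- svintegrate:::pair_anomalous_alignments(lr$truth_aln)
  w <- compute_window(lr$stats$avg_molecule_length,
                      lr$stats$n50_reads_per_molecule)
  gq <- gem_quantify_svs(mlr, pairs, lr$total_gems, w)
  ## coverage features from the truth alignments
  cov_tab <- function(ta) {
    data.frame(chrom = ta$chrom, pos = ta$pos,
               end = ta$pos + nchar(ta$seq) - 1L)
  }
  mean_depth_sr <- nrow(sr$reads) * cfg$read_length / sum(nchar(g))
  mean_depth_lr <- nrow(lr$truth_aln) * 140 / sum(nchar(g))
  an_sr <- annotate_svs(msr, alignments = cov_tab(sr$truth_aln),
                        sample_mean_depth = mean_depth_sr)
  an_lr <- annotate_svs(mlr, alignments = cov_tab(lr$truth_aln),
                        sample_mean_depth = mean_depth_lr)
  lab_sr <- label_merged(msr, cs$labels)
  lab_lr <- label_merged(mlr, cs$labels)
  fs <- build_features(msr, rq_sr, an_sr, technology = "SR", labels = lab_sr)
  fl <- build_features(mlr, rq_lr, an_lr, gem = gq, technology = "LR",
                       labels = lab_lr)
  m_sr <- train_model(fs, "SR", seed = seed)
  m_lr <- train_model(fl, "LR", seed = seed)
  p_sr <- predict(m_sr, fs); p_lr <- predict(m_lr, fl)
  lr_key <- ifelse(cmp$category == "ONLY_LR", cmp$id, cmp$partner_id)
  comb <- combined_predict(cmp$category,
                           p_sr[match(cmp$id, names(p_sr))],
                           p_lr[match(lr_key, names(p_lr))])
  ## per-record labels and truth ids
  rec_lab <- ifelse(cmp$category == "ONLY_LR",
                    lab_lr$label[match(cmp$id, lab_lr$sv_id)],
                    lab_sr$label[match(cmp$id, lab_sr$sv_id)])
  rec_truth <- ifelse(cmp$category == "ONLY_LR",
                      lab_lr$truth_id[match(cmp$id, lab_lr$sv_id)],
                      lab_sr$truth_id[match(cmp$id, lab_sr$sv_id)])
  retained_truth <- unique(rec_truth[comb == "POSITIVE" & !is.na(rec_truth)])
  decoy_records <- which(rec_lab == "NEGATIVE")
  list(cfg = cfg, truth = imp$truth, cmp = cmp, combined = comb,
       labels = rec_lab, truth_ids = rec_truth,
       n_truth = nrow(imp$truth),
       n_truth_retained = length(retained_truth),
       n_decoy = length(decoy_records),
       n_decoy_rejected = sum(comb[decoy_records] == "NEGATIVE"),
       common_ids = cmp$id[cmp$category == "COMMON"],
       positive_ids = cmp$id[comb == "POSITIVE"],
       models = list(SR = m_sr, LR = m_lr),
       features = list(SR = fs, LR = fl),
       requant = list(SR = rq_sr, LR = rq_lr), gem = gq)
}
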