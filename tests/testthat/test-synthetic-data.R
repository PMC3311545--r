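test_that("configuration invariants are enforced", {
  expect_s3_class(test_config(), "sim_config")
  expect_error(test_config(motif_coverage = 1.5), "probabilities")
  expect_error(test_config(gc_content = 0), "gc_content")
  expect_error(sim_config(class_proportions = c(maternal = 0.5, silent = 0.5)),
               "named over")
  bad <- c(maternal = 0.5, ezg_transient = 0.1, ezg_stable = 0.1,
           first_4_8 = 0.1, first_8_12 = 0.1, silent = 0.2)
  expect_error(sim_config(class_proportions = bad), "sum to 1")
  expect_error(test_config(library_sizes = c(-1, 1, 1, 1)), "positive")
  expect_error(test_config(upstream_length = 3), "motif length")
  expect_error(test_config(motif_consensus = "VBXGGTA"), "invalid IUPAC")
})

test_that("simulated counts honour class profiles and are deterministic", {
  cfg <- test_config()
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$class_of, b$truth$class_of)

  cls <- a$truth$class_of
  cnt <- a$counts$counts
  # ezg_* and later classes are structurally zero before their first bin
  expect_true(all(cnt[startsWith(cls, "ezg_"), "h0_2"] == 0))
  expect_true(all(cnt[cls == "first_4_8", c("h0_2", "h2_4")] == 0))
  expect_true(all(cnt[cls == "first_8_12", c("h0_2", "h2_4", "h4_8")] == 0))
  expect_true(all(cnt[cls == "silent", ] == 0))

  # oracle: re-apply the presence rule; every ezg transcript detected at
  # 2-4 hr must be labelled candidate_2_4 and vice versa
  detected <- cnt[, "h0_2"] == 0 & cnt[, "h2_4"] >= 1
  lab <- classify_transcripts(a$counts)
  expect_setequal(names(lab)[lab == "candidate_2_4"],
                  a$counts$transcript_ids[detected])

  # column sums within 5 Poisson standard deviations of library sizes
  expect_true(all(abs(colSums(cnt) - cfg$library_sizes) <=
                    5 * sqrt(cfg$library_sizes)))
})

test_that("all-silent scenario yields an all-zero matrix", {
  props <- c(maternal = 0, ezg_transient = 0, ezg_stable = 0,
             first_4_8 = 0, first_8_12 = 0, silent = 1)
  sim <- simulate_counts(test_config(class_proportions = props))
  expect_true(all(sim$counts$counts == 0))
})

test_that("upstream plants match coverage, IUPAC semantics and strand", {
  cfg <- test_config(motif_coverage = 0.635)
  ups <- simulate_upstream(cfg, 1000)
  frac <- length(unique(ups$truth$planted_hits$seq_id)) / 1000
  # binomial oracle: within 3 standard deviations of the configured rate
  expect_lt(abs(frac - 0.635), 3 * sqrt(0.635 * 0.365 / 1000))

  # construction invariant: every plant matches the consensus on its strand
  seqs <- as.character(ups$sequences)
  L <- nchar(cfg$motif_consensus)
  words <- substring(seqs[ups$truth$planted_hits$seq_id],
                     ups$truth$planted_hits$start + 1L,
                     ups$truth$planted_hits$start + L)
  minus <- ups$truth$planted_hits$strand == "-"
  words[minus] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(words[minus])))
  expect_true(all(words %in% iupac_expand(cfg$motif_consensus)))

  # zero coverage plants nothing; determinism
  none <- simulate_upstream(test_config(motif_coverage = 0), 50)
  expect_identical(nrow(none$truth$planted_hits), 0L)
  again <- simulate_upstream(cfg, 1000)
  expect_identical(as.character(again$sequences), seqs)
})

test_that("annotations carry the configured intronless enrichment", {
  cfg <- test_config(p_intronless_ezg = 1)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  ezg_tx <- names(sim$truth$class_of)[startsWith(sim$truth$class_of, "ezg_")]
  ezg_genes <- ann$annotations$gene_id[match(ezg_tx, ann$annotations$transcript_id)]
  expect_true(all(ann$truth$intronless_of[ezg_genes]))

  # intron count is 0 iff the intronless flag is set
  flag <- ann$truth$intronless_of[ann$annotations$gene_id]
  expect_identical(unname(ann$annotations$n_introns == 0L), unname(flag))

  # binomial oracle on the background rate
  cfg2 <- test_config()
  sim2 <- simulate_counts(cfg2)
  ann2 <- simulate_annotations(cfg2, sim2$truth)
  bg_genes <- ann2$annotations$gene_id[
    !startsWith(sim2$truth$class_of[ann2$annotations$transcript_id], "ezg_")]
  p_bg <- mean(ann2$truth$intronless_of[unique(bg_genes)])
  expect_lt(abs(p_bg - 0.10), 3 * sqrt(0.1 * 0.9 / length(unique(bg_genes))))
})

test_that("multi-transcript genes share intronless status", {
  cfg <- test_config()
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth, transcripts_per_gene = 3L)
  per_gene <- tapply(ann$annotations$n_introns == 0L, ann$annotations$gene_id,
                     function(z) length(unique(z)))
  expect_true(all(per_gene == 1L))
})
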