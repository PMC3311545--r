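# End-to-end orchestration: filter -> MARS -> intron structure -> motif
# discovery -> PWM alignment, plus a subcommand-style CLI wrapper.

#' Pipeline configuration
#'
#' @param counts Path to the counts TSV.
#' @param annotations Optional path to an annotation TSV/GFF3.
#' @param upstream Optional path to an upstream-sequence FASTA (sequence
#'   names = transcript ids).
#' @param background Optional path to a background FASTA for the motif
#'   null; default uses the analyzed set itself.
#' @param library_sizes Optional path to a library-size TSV.
#' @param out_dir Output directory.
#' @param pseudocount MARS pseudocount.
#' @param thresholds Ascending raw p-value thresholds.
#' @param motif_length_range,beam_width,max_degenerate_positions Motif
#'   search parameters (see [discover_motifs]).
#' @param tagteam_consensi Consensus strings the top discovered motif's PWM
#'   is aligned against (default: the three classic TAGteam heptamers).
#' @param pwm_n_null Permutations for the alignment E-value.
#' @param seed Global seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotations = NULL, upstream = NULL,
                            background = NULL, library_sizes = NULL,
                            out_dir = "ezgkit_out", pseudocount = 1,
                            thresholds = c(0.001, 0.05),
                            motif_length_range = c(5, 10), beam_width = 50,
                            max_degenerate_positions = 4,
                            tagteam_consensi = c("CAGGTAG", "TAGGTAG", "CAGGCAG"),
                            pwm_n_null = 10000, seed = 1) {
  assert_that(!is.unsorted(thresholds), "thresholds must be ascending")
  structure(list(counts = counts, annotations = annotations,
                 upstream = upstream, background = background,
                 library_sizes = library_sizes, out_dir = out_dir,
                 pseudocount = pseudocount, thresholds = thresholds,
                 motif_length_range = motif_length_range,
                 beam_width = beam_width,
                 max_degenerate_positions = max_degenerate_positions,
                 tagteam_consensi = tagteam_consensi,
                 pwm_n_null = pwm_n_null, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' CLI flags override file values; see [ezg_cli].
#'
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  assert_that(length(unknown) == 0L,
              "unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full early-zygotic discovery pipeline
#'
#' Stages: read counts -> normalize -> temporal classification -> MARS on
#' (0-2, 2-4) -> EZG call sets -> first-presence groups -> gene-structure
#' summary and enrichment tests (if annotations given) -> degenerate motif
#' discovery on the significant EZGs' upstream sequences -> PWM of the top
#' motif's hits aligned against the TAGteam consensi (if upstream sequences
#' given). All outputs land under `config$out_dir` together with a JSON run
#' manifest (package version, seed, parameter echo, input checksums).
#'
#' @param config A [pipeline_config].
#' @return Invisible list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  for (p in c(config$counts, config$annotations, config$upstream,
              config$background, config$library_sizes))
    assert_that(is.null(p) || file.exists(p), "input file not found: ", p %||% "")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list()

  counts <- read_counts(config$counts, library_sizes = config$library_sizes)
  norm <- normalize_counts(counts)
  utils::write.table(
    data.frame(transcript_id = counts$transcript_ids, round(norm, 6),
               check.names = FALSE),
    out("normalized_rpkm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  mars <- mars_table(counts, pseudocount = config$pseudocount)
  write_mars_table(mars, out("mars_0_2_vs_2_4.tsv"), thresholds = config$thresholds)
  calls <- call_ezgs(counts, mars, thresholds = config$thresholds)
  write_classification(counts, mars, out("classification.tsv"),
                       thresholds = config$thresholds)
  groups <- group_by_first_presence(counts, threshold = config$thresholds[1L],
                                    pseudocount = config$pseudocount)
  grp_df <- do.call(rbind, lapply(names(groups), function(g)
    if (length(groups[[g]]))
      data.frame(group = g, transcript_id = groups[[g]]) else NULL))
  utils::write.table(grp_df %||% data.frame(group = character(0),
                                            transcript_id = character(0)),
                     out("first_presence_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results <- c(results, list(counts = counts, mars = mars, calls = calls,
                             groups = groups))

  strict <- as.character(config$thresholds[1L])
  ezg_ids <- calls$significant[[strict]]

  annotations <- NULL
  if (!is.null(config$annotations)) {
    annotations <- read_annotations(config$annotations)
    gene_groups <- list(
      ezg = unique(collapse_to_genes(ezg_ids, annotations)$gene_id),
      h4_8 = unique(collapse_to_genes(groups$h4_8, annotations)$gene_id),
      h8_12 = unique(collapse_to_genes(groups$h8_12, annotations)$gene_id))
    gene_groups <- gene_groups[vapply(gene_groups, length, 1L) > 0]
    structure_res <- compare_groups(annotations, gene_groups)
    utils::write.table(structure_res$summary, out("gene_structure_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(structure_res$tests, out("gene_structure_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$gene_structure <- structure_res
  }

  if (!is.null(config$upstream)) {
    upstream <- Biostrings::readDNAStringSet(config$upstream)
    target <- upstream[intersect(names(upstream), ezg_ids)]
    assert_that(length(target) >= 2L,
                "fewer than two upstream sequences for significant EZGs")
    bg <- if (!is.null(config$background))
      background_model(Biostrings::readDNAStringSet(config$background))
    else NULL
    motifs <- discover_motifs(target, background = bg,
                              length_range = config$motif_length_range,
                              beam_width = config$beam_width,
                              max_degenerate_positions = config$max_degenerate_positions)
    write_motif_table(motifs, out("motif_table.tsv"))
    top_motif <- motifs$motif[1L]
    hits <- scan_motif(top_motif, target)
    write_hits_bed(hits, top_motif, out("top_motif_hits.bed"))
    if (nrow(hits) > 0L) {
      qp <- pwm_from_hits(hits, target, motif_length = nchar(top_motif),
                          name = top_motif)
      targets <- lapply(config$tagteam_consensi, pwm_from_iupac)
      alignments <- lapply(targets, function(t)
        pwm_alignment_evalue(qp, t, n_null = config$pwm_n_null,
                             seed = config$seed))
      write_meme(c(list(qp), targets), out("motifs.meme"))
      write_alignment_report(alignments, out("pwm_alignments.tsv"))
      results$pwm <- qp
      results$alignments <- alignments
    }
    results$motifs <- motifs
  }

  inputs <- Filter(Negate(is.null),
                   list(counts = config$counts, annotations = config$annotations,
                        upstream = config$upstream, background = config$background,
                        library_sizes = config$library_sizes))
  manifest <- list(
    package = "ezgkit",
    version = as.character(utils::packageVersion("ezgkit")),
    seed = config$seed,
    parameters = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    n_candidates = length(calls$candidates),
    n_significant = lapply(calls$significant, length)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
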