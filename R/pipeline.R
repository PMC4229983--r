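# End-to-end orchestration: simulate -> characterize -> annotate ->
# classify -> summarize, plus the fixture report that recomputes the
# study-level counts from the packaged deletion table.

.md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

# map a junction call + planted-feature annotation to a feature vector
.call_features <- function(call, truth_row, features, annotation) {
  ins_len <- if (is.null(call$insertion_seq)) 0L else
    nchar(call$insertion_seq)
  micro <- ins_len >= 1L && ins_len <= 100L
  mh <- if (micro || ins_len == 0L) {
    if (ins_len > 0L) call$flank_mh else call$mh_len
  } else 0L
  sine_pair <- NULL
  alu <- features[features$kind == "alu" &
                    features$junction_id == call$junction_id, , drop = FALSE]
  if (nrow(alu) >= 2L) {
    # breakpoints on the contig, from the flank origins recorded with the
    # emitted flanks (input metadata, not simulator truth)
    prox_ctg <- truth_row$flank_prox_start + call$breakpoint_proximal - 1L
    dist_ctg <- truth_row$flank_dist_start + call$breakpoint_distal - 1L
    for (pid in unique(alu$pair_id)) {
      pair <- alu[alu$pair_id == pid, , drop = FALSE]
      if (nrow(pair) != 2L) next
      in1 <- prox_ctg + 1L >= pair$start[1L] & prox_ctg + 1L <= pair$end[1L]
      in2 <- dist_ctg >= pair$start[2L] & dist_ctg <= pair$end[2L]
      if (in1 && in2) {
        sine_pair <- list(
          identity_percent = pair$identity[1L],
          alignment_len_bp = pair$end[1L] - pair$start[1L] + 1L,
          orientation = if (all(pair$strand == pair$strand[1L]))
            "direct" else "inverted")
        break
      }
    }
  }
  feature_vector(
    mh_len = mh,
    insertion_len = if (micro) ins_len else 0L,
    insertion_templated = micro && nrow(call$template_hits) > 0L,
    snc_present = nrow(call$sncs) > 0L,
    sva_detected = !is.null(annotation),
    sine_pair = sine_pair
  )
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort ([build_cohort()]), dissects every junction
#' ([characterize_junction()]), annotates SVA insertions
#' ([annotate_sva()]), classifies mechanisms ([classify_mechanism()]) and
#' compares the calls against the simulator ground truth.
#'
#' @param cfg A [sim_config()].
#' @param sources Optional SVA source library (defaults to the cohort's).
#' @param thresholds Classifier thresholds.
#' @param out_dir Optional directory; when given, cohort files, the call
#'   table and the summary JSON are written there.
#' @return List with class `pipeline_result`: `cohort`, `calls`,
#'   `annotations`, `mechanisms` (per-junction truth/called table),
#'   `summary` (per-mechanism recovery, TPRT hallmark rates), `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), sources = NULL,
                         thresholds = classifier_thresholds(),
                         out_dir = NULL) {
  cohort <- build_cohort(cfg, sources = sources)
  jids <- names(cohort$junctions)
  calls <- list(); annotations <- list(); rows <- list()
  for (jid in jids) {
    jseq <- cohort$junctions[[jid]]$seq
    P <- cohort$flanks[[paste0(jid, "__prox")]]$seq
    D <- cohort$flanks[[paste0(jid, "__dist")]]$seq
    truth_row <- cohort$truth[cohort$truth$junction_id == jid, , drop = FALSE]
    call <- tryCatch(
      characterize_junction(jid, jseq, P, D),
      error = function(e) stop("stage characterize failed for ", jid, ": ",
                               conditionMessage(e), call. = FALSE))
    ann <- annotate_sva(jseq, cohort$sources)
    fv <- .call_features(call, truth_row, cohort$features, ann)
    mech <- classify_mechanism(fv, thresholds)
    calls[[jid]] <- call
    annotations[[jid]] <- ann
    hall <- if (!is.null(ann)) tprt_hallmarks(jseq, ann, prox_flank = P)
            else NULL
    rows[[jid]] <- data.frame(
      junction_id = jid,
      truth_mechanism = truth_row$mechanism,
      called_mechanism = mech,
      correct = truth_row$mechanism == mech,
      mh_called = fv$mh_len,
      mh_planted = truth_row$flank_mh,
      insertion_called = if (is.null(call$insertion_seq)) NA_character_
                         else call$insertion_seq,
      n_sncs_called = nrow(call$sncs),
      sva_source_called = if (is.null(ann)) NA_character_ else ann$source_id,
      en_site = if (is.null(hall)) NA else hall$en_site_at_integration,
      polyt = if (is.null(hall)) NA else hall$polyt_tract,
      stringsAsFactors = FALSE)
  }
  mechanisms <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  per_mech <- lapply(split(mechanisms, mechanisms$truth_mechanism),
                     function(df) {
                       c(n = nrow(df), correct = sum(df$correct),
                         recovery = sum(df$correct) / nrow(df))
                     })
  sva_rows <- mechanisms[mechanisms$truth_mechanism == "SVA_INSERTION", ]
  summary <- list(
    n_junctions = nrow(mechanisms),
    mechanisms_present = sort(unique(mechanisms$truth_mechanism)),
    per_mechanism = per_mech,
    overall_recovery = mean(mechanisms$correct),
    mh_exact_rate = mean(mechanisms$mh_called == mechanisms$mh_planted),
    tprt_en_site_rate = if (nrow(sva_rows)) mean(sva_rows$en_site) else NA,
    tprt_polyt_rate = if (nrow(sva_rows)) mean(sva_rows$polyt) else NA,
    sva_source_correct_rate = if (nrow(sva_rows)) {
      mean(sva_rows$sva_source_called ==
             cohort$truth$sva_source[match(sva_rows$junction_id,
                                           cohort$truth$junction_id)])
    } else NA
  )
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    n_junctions = length(jids),
    junctions_digest = .md5_of_string(
      paste(vapply(cohort$junctions, `[[`, character(1L), "seq"),
            collapse = "\n")),
    truth_digest = .md5_of_string(
      paste(utils::capture.output(utils::write.table(cohort$truth, sep = "\t",
                                                     row.names = FALSE)),
            collapse = "\n"))
  )
  res <- structure(list(cohort = cohort, calls = calls,
                        annotations = annotations,
                        mechanisms = mechanisms, summary = summary,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, out_dir)
    utils::write.table(mechanisms, file.path(out_dir, "mechanism_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d junctions, overall recovery %.1f%%\n",
              x$summary$n_junctions, 100 * x$summary$overall_recovery))
  invisible(x)
}

#' Summary statistics over a deletion feature table
#'
#' Recomputes the study-level counts from a deletion record table:
#' deletion sizes from coordinates, microhomology class counts, SNC and
#' mosaicism counts, proximal-breakpoint locus counts, and the densest
#' telomeric 5-breakpoint window among the deletions whose distal
#' breakpoints stay within the annotated core region (distal to it the
#' coordinates are excluded from the clustering, mirroring the two
#' outlier deletions).
#'
#' @param records List of [deletion_record()]s (default the packaged
#'   fixture).
#' @param annotation Interval annotation for locus labeling (default the
#'   packaged synthetic proxy).
#' @param cluster_k Breakpoints per cluster window (default 5).
#' @return List of counts and derived quantities; percentages are rounded
#'   to the nearest integer percent.
#' @export
deletion_table_report <- function(records = nf1_deletion_fixture(),
                          annotation = nf1_region_annotation(),
                          cluster_k = 5L) {
  n <- length(records)
  mh <- vapply(records, function(r)
    if (is.na(r$microhomology_len)) 0 else r$microhomology_len, numeric(1L))
  mh_na <- vapply(records, function(r) is.na(r$microhomology_len),
                  logical(1L))
  snc <- vapply(records, function(r) r$snc_present, logical(1L))
  mosaic <- vapply(records, function(r) r$mosaic, logical(1L))
  sva <- vapply(records, function(r) !is.na(r$sva_family), logical(1L))
  prox <- vapply(records, function(r) r$proximal_bp, numeric(1L))
  dist <- vapply(records, function(r) r$distal_bp, numeric(1L))
  sizes <- deletion_size(prox, dist)
  printed <- vapply(records, function(r)
    if (is.null(r$size_printed)) NA_real_ else r$size_printed, numeric(1L))
  prox_labels <- vapply(prox, locate_breakpoint_in_annotation,
                        character(1L), annotation = annotation)
  region_end <- max(annotation$end[annotation$label == "NF1REPc"])
  in_region <- dist <= region_end
  cluster <- min_span_window(dist[in_region], cluster_k)
  list(
    n_records = n,
    n_simple_breakpoint = sum(!sva),
    n_sva_insertion = sum(sva),
    n_mh_1_4 = sum(!mh_na & mh >= 1 & mh <= 4),
    n_mh_ge6 = sum(!mh_na & mh >= 6),
    n_snc = sum(snc),
    n_mosaic = sum(mosaic),
    mosaic_percent = round_half_up(100 * sum(mosaic) / n),
    n_proximal_suz12p = sum(prox_labels == "SUZ12P"),
    sizes = sizes,
    n_sizes_match_printed = sum(!is.na(printed) & printed == sizes),
    telomeric_cluster_span = cluster$span,
    telomeric_cluster_kb = cluster$span_kb,
    telomeric_cluster_members = cluster$members,
    n_in_region_telomeric = sum(in_region)
  )
}
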