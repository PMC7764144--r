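# Orchestration: the per-knockdown mode-decision rule, cross-experiment
# overlap statistics over the annotated human gene universe, and the
# end-to-end pipeline.

#' GENCODE v35 human gene-category counts
#'
#' Protein-coding, long non-coding and small non-coding gene counts whose
#' sum (45480) is the default universe for gene-overlap tests.
#'
#' @format Named integer vector of length 3.
#' @export
gencode_v35_gene_counts <- c(protein_coding = 19954L, lncRNA = 17957L,
                             small_ncRNA = 7569L)

#' Default gene universe for overlap tests
#'
#' @return Sum of [gencode_v35_gene_counts] (45480).
#' @export
default_gene_universe <- function() sum(gencode_v35_gene_counts)

#' Hypergeometric p-value for the overlap of two gene sets
#'
#' X ~ Hypergeometric(universe, size_a, size_b) is the null overlap of two
#' independent sets of the given sizes. `tail = "gt"` returns the strictly-
#' greater tail P(X > k) (the phyper upper-tail call pattern used for the
#' reported overlaps); `tail = "ge"` the conventional P(X >= k). Exact.
#'
#' @param k Observed intersection size.
#' @param size_a,size_b Set sizes.
#' @param universe Universe size (default [default_gene_universe()]).
#' @param tail "gt" (strictly greater) or "ge".
#' @return p in (0, 1].
#' @export
overlap_pvalue <- function(k, size_a, size_b,
                           universe = default_gene_universe(),
                           tail = c("gt", "ge")) {
  tail <- match.arg(tail)
  if (k > min(size_a, size_b) || size_a > universe || size_b > universe ||
      k < 0)
    stop("inconsistent overlap counts: k=", k, " |A|=", size_a, " |B|=",
         size_b, " universe=", universe, call. = FALSE)
  q <- if (tail == "gt") k else k - 1
  if (q < 0) return(1)
  phyper(q, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

#' Concordant down-regulation across experiments
#'
#' Counts the shared genes whose log2 fold-change is strictly negative in
#' every supplied table, the signature of a knocked-down activator.
#'
#' @param tables List of data.frames, each with an id column (first column
#'   or `promoter_id`/`gene_id`) and a `log2fc` column.
#' @param shared_ids Genes present in all tables to evaluate.
#' @return List: n_shared, concordant_down_count, concordant_down_pct
#'   (percentage rounded to one decimal; absent when n_shared = 0).
#' @export
concordance_summary <- function(tables, shared_ids) {
  if (length(shared_ids) == 0)
    return(list(n_shared = 0L, concordant_down_count = 0L,
                concordant_down_pct = NULL))
  down_all <- rep(TRUE, length(shared_ids))
  for (tab in tables) {
    idcol <- intersect(c("promoter_id", "gene_id"), names(tab))
    ids <- if (length(idcol) > 0) tab[[idcol[1]]] else tab[[1]]
    m <- match(shared_ids, ids)
    if (any(is.na(m)))
      stop("shared id(s) missing from a table: ",
           paste(head(shared_ids[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    down_all <- down_all & (tab$log2fc[m] < 0)
  }
  cnt <- sum(down_all)
  list(n_shared = length(shared_ids), concordant_down_count = cnt,
       concordant_down_pct = round(100 * cnt / length(shared_ids), 1))
}

#' Decide the interaction mode of a knockdown
#'
#' Deterministic rule over the two enrichment results and (when both modes
#' are significant) the contact-peak co-localization:
#' co only -> "co"; post only -> "post"; both significant -> "co_via_coloc"
#' if the co-localization p (reldist) < alpha else "ambiguous" (with a
#' warning when no co-localization result is available); neither -> "none".
#'
#' @param co,post `enrichment_result`s for the same knockdown.
#' @param coloc A `coloc_result` or NULL.
#' @param alpha Threshold shared by all stages.
#' @return A `mode_call` list: aso_id, call, co, post, coloc.
#' @export
decide_mode <- function(co, post, coloc = NULL, alpha = 0.01) {
  stopifnot(inherits(co, "enrichment_result"),
            inherits(post, "enrichment_result"))
  if (!identical(co$aso_id, post$aso_id))
    stop("mismatched aso_ids: ", co$aso_id, " vs ", post$aso_id,
         call. = FALSE)
  call <- if (co$significant && !post$significant) "co"
    else if (!co$significant && post$significant) "post"
    else if (co$significant && post$significant) {
      if (is.null(coloc)) {
        warning("both modes significant but no co-localization result; ",
                "call is ambiguous")
        "ambiguous"
      } else if (coloc$perm_p_reldist < alpha) "co_via_coloc" else "ambiguous"
    } else "none"
  structure(list(aso_id = co$aso_id, call = call, co = co, post = post,
                 coloc = coloc, alpha = alpha),
            class = "mode_call")
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf(
    "<mode_call> %s: %s (co: hgd=%.3g gsea=%.3g | post: hgd=%.3g gsea=%.3g%s)\n",
    if (is.na(x$aso_id)) "?" else x$aso_id, x$call, x$co$hgd_p, x$co$gsea_p,
    x$post$hgd_p, x$post$gsea_p,
    if (!is.null(x$coloc)) sprintf(" | coloc p=%.3g", x$coloc$perm_p_reldist)
    else ""))
  invisible(x)
}

#' Run the full per-knockdown analysis
#'
#' Builds the co- and post-transcriptional target sets for every promoter in
#' the knockdown background, predicts antisense interactions of the lncRNA
#' against both, tests hit enrichment among the DEGs in both modes, runs the
#' contact-peak co-localization test when both modes are significant (and
#' peaks are provided), and applies the mode-decision rule. Deterministic
#' given the seed.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Named list of `gene_model`s.
#' @param lncrna Query lncRNA sequence.
#' @param kd A `knockdown_table`.
#' @param peaks Optional `peak_set` of RNA-chromatin contact peaks.
#' @param params Duplex predictor parameters, see [duplex_params()].
#' @param alpha Significance threshold shared across stages.
#' @param window_len Co-transcriptional window length, bp.
#' @param flank Promoter flank for co-localization intervals, bp.
#' @param n_perm_gsea,n_perm_coloc Permutation counts.
#' @param seed Master seed; stage streams derived by fixed offsets.
#' @param out_dir Optional directory for all intermediate tables.
#' @return List: mode_call, co, post (enrichment results), hits_co,
#'   hits_post, coloc (or NULL), params echo.
#' @export
run_pipeline <- function(genome, genes, lncrna, kd, peaks = NULL,
                         params = duplex_params(), alpha = 0.01,
                         window_len = 1000L, flank = 500L,
                         n_perm_gsea = 1000L, n_perm_coloc = 100L,
                         seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pids <- kd$promoter_id
  targets_co <- stage("targets(co)",
    build_target_set(genes, pids, genome, "co", window_len))
  targets_post <- stage("targets(post)",
    build_target_set(genes, pids, genome, "post"))
  hits_co <- stage("predict(co)",
    predict_interactions(lncrna, targets_co, params, seed = seed))
  hits_post <- stage("predict(post)",
    predict_interactions(lncrna, targets_post, params, seed = seed + 1L))
  co <- stage("enrich(co)",
    evaluate_knockdown_mode(hits_co, kd, "co", alpha = alpha,
                            hit_alpha = params$hit_alpha,
                            n_perm = n_perm_gsea, seed = seed + 2L))
  post <- stage("enrich(post)",
    evaluate_knockdown_mode(hits_post, kd, "post", alpha = alpha,
                            hit_alpha = params$hit_alpha,
                            n_perm = n_perm_gsea, seed = seed + 3L))
  coloc <- NULL
  if (co$significant && post$significant && !is.null(peaks) &&
      nrow(peaks) > 0) {
    deg <- kd$promoter_id[kd$deg_flag]
    hit_prom <- hits_co$target_id[hits_co$p_adj < params$hit_alpha]
    cand <- intersect(deg, hit_prom)
    if (length(cand) > 0) {
      query <- stage("coloc",
        promoter_intervals(genes, flank, genome, promoter_ids = cand))
      coloc <- stage("coloc",
        permutation_test(query, peaks, chrom_sizes(genome),
                         n_perm = n_perm_coloc, seed = seed + 4L,
                         aso_id = attr(kd, "aso_id")))
    }
  }
  mc <- decide_mode(co, post, coloc, alpha = alpha)
  res <- list(mode_call = mc, co = co, post = post, hits_co = hits_co,
              hits_post = hits_post, coloc = coloc,
              settings = list(alpha = alpha, window_len = window_len,
                              flank = flank, n_perm_gsea = n_perm_gsea,
                              n_perm_coloc = n_perm_coloc, seed = seed,
                              params = params))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hits_tsv(hits_co, file.path(out_dir, "hits_co.tsv"))
    write_hits_tsv(hits_post, file.path(out_dir, "hits_post.tsv"))
    enr <- do.call(rbind, lapply(list(co, post), function(e)
      data.frame(aso_id = e$aso_id, mode = e$mode,
                 n_background = e$n_background, n_deg = e$n_deg,
                 n_hits_background = e$n_hits_background,
                 n_hits_in_deg = e$n_hits_in_deg, hgd_p = e$hgd_p,
                 gsea_es = e$gsea_es, gsea_p = e$gsea_p,
                 significant = e$significant)))
    write_results_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(coloc)) {
      cr <- data.frame(aso_id = coloc$aso_id,
                       n_query_intervals = coloc$n_query_intervals,
                       n_reference_peaks = coloc$n_reference_peaks,
                       overlap_stat = coloc$overlap_stat,
                       reldist_stat = coloc$reldist_stat,
                       perm_p_overlap = coloc$perm_p_overlap,
                       perm_p_reldist = coloc$perm_p_reldist,
                       n_perm = coloc$n_perm)
      write_results_tsv(cr, file.path(out_dir, "coloc.tsv"))
    }
    manifest <- res$settings
    manifest$call <- mc$call
    manifest$aso_id <- mc$aso_id
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(paste0("call\t", mc$call), file.path(out_dir, "mode_call.tsv"))
  }
  res
}
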