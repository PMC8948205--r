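#' Preset scenario: one causal variant shared by both proteins
#'
#' A single mid-region variant drives several glycan peaks of both proteins
#' (effects 0.35-0.5 on the standardised latent scale), emulating a locus
#' where the same regulatory variant shapes the modification on both
#' carriers. The expected cascade outcome is a between-protein
#' colocalisation verdict.
#'
#' @param seed master seed.
#' @param ... overrides passed to [sim_scenario()].
#' @return a `sim_scenario`.
#' @export
scenario_shared <- function(seed = 1L, ...) {
  cm <- rbind(
    data.frame(snp_index = 126L, trait_id = paste0("TfGP", 1:4),
               beta = c(0.5, 0.45, 0.4, 0.35)),
    data.frame(snp_index = 126L, trait_id = paste0("GP", 1:3),
               beta = c(0.45, 0.4, 0.35)))
  sim_scenario(causal_map = cm, seed = seed, ...)
}

#' Preset scenario: distinct causal variants in one gene region
#'
#' Two variants 260 kb apart (negligible LD) drive the two proteins'
#' glycan peaks separately — the situation where one gene region associates
#' with both proteins but the regulation is variant-specific. The expected
#' cascade outcome is a "distinct" verdict (high PP.H3).
#'
#' @param seed master seed.
#' @param ... overrides passed to [sim_scenario()].
#' @return a `sim_scenario`.
#' @export
scenario_distinct <- function(seed = 1L, ...) {
  cm <- rbind(
    data.frame(snp_index = 60L, trait_id = paste0("TfGP", 1:4),
               beta = c(0.5, 0.45, 0.4, 0.35)),
    data.frame(snp_index = 190L, trait_id = paste0("GP", 1:3),
               beta = c(0.45, 0.4, 0.35)))
  sim_scenario(causal_map = cm, seed = seed, ...)
}

#' Assemble a run configuration
#'
#' @param scenario a [sim_scenario()].
#' @param alpha base genome-wide significance level (default 5e-8); the
#'   per-protein threshold is `alpha / n_traits`.
#' @param cascade_p regional association threshold for entering the
#'   colocalisation cascade (default 5e-8).
#' @param priors a [coloc_priors()].
#' @param pp_threshold posterior-probability evidence threshold (0.8).
#' @param cojo_p threshold for secondary-signal selection in the cascade
#'   (default 5e-8).
#' @param collinearity COJO collinearity cap (0.9).
#' @param n_ref LD-reference cohort size (default 2000).
#' @param out_dir optional output directory for [write_report()].
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario, alpha = 5e-8, cascade_p = 5e-8,
                       priors = coloc_priors(), pp_threshold = 0.8,
                       cojo_p = 5e-8, collinearity = 0.9, n_ref = 2000L,
                       out_dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  for (v in c(alpha, cascade_p, cojo_p, pp_threshold))
    if (v <= 0 || v >= 1) stop_arg("thresholds must lie in (0,1)")
  structure(list(scenario = scenario, alpha = alpha, cascade_p = cascade_p,
                 priors = priors, pp_threshold = pp_threshold,
                 cojo_p = cojo_p, collinearity = collinearity,
                 n_ref = as.integer(n_ref), out_dir = out_dir),
            class = "run_config")
}

# per-cohort GWAS of every trait of one protein
cohort_gwas <- function(cohort, protein) {
  ph <- cohort$phenotypes[[protein]]
  lapply(stats::setNames(colnames(ph), colnames(ph)), function(tr) {
    y <- rank_inverse_normal(ph[, tr])
    r <- adjust_covariates(y, cohort$covariates)
    gwas_additive(r, cohort$dosages, cohort$snp,
                  trait_id = tr, cohort_id = cohort$cohort_id)
  })
}

# meta-analysis of one trait across the cohorts, with QC and GC
meta_trait <- function(per_cohort) {
  qc <- qc_filter(per_cohort[[1]], per_cohort[[2]])
  m <- ivw_meta(list(qc$a, qc$b),
                trait_id = attr(per_cohort[[1]], "trait_id"))
  genomic_control(m)
}

# within-protein cascade at one region: group traits by colocalisation,
# separately for single- and multi-signal traits, then across the two
# pools; returns the protein's representative trait and bookkeeping.
within_protein_cascade <- function(meta_list, trait_p, signals, priors,
                                   pp_threshold) {
  pool_of <- ifelse(signals[names(meta_list)] > 1, "multi", "single")
  reps <- character()
  pools <- split(names(meta_list), pool_of)
  pairwise_all <- NULL
  group_pool <- function(trs) {
    if (length(trs) == 1)
      return(list(rep = trs, groups = list(trs), pairwise = NULL))
    pw <- NULL
    for (i in seq_len(length(trs) - 1)) for (j in (i + 1):length(trs)) {
      res <- suppressWarnings(
        coloc_abf(meta_list[[trs[i]]], meta_list[[trs[j]]], priors))
      pw <- rbind(pw, data.frame(t1 = trs[i], t2 = trs[j],
                                 pp4 = res$pp[["PP.H4"]]))
    }
    gr <- coloc_group(trs, pw, trait_p[trs], pp_threshold)
    list(rep = gr$representative, groups = gr$groups, pairwise = pw)
  }
  stage1 <- lapply(pools, group_pool)
  reps <- unlist(lapply(stage1, `[[`, "rep"), use.names = FALSE)
  for (st in stage1) pairwise_all <- rbind(pairwise_all, st$pairwise)
  if (length(reps) > 1) {             # single- vs multi-signal representatives
    st2 <- group_pool(reps)
    pairwise_all <- rbind(pairwise_all, st2$pairwise)
    reps <- st2$rep
  }
  final_rep <- reps[order(trait_p[reps], reps)][1]
  list(representative = final_rep, stage1 = stage1,
       pairwise = pairwise_all)
}

#' Run the full two-protein comparison cascade
#'
#' Executes, from a single configuration: cohort simulation, per-cohort
#' GWAS (rank-INT, covariate adjustment, additive Wald test), cross-cohort
#' QC + IVW meta-analysis + genomic control, per-trait locus definition and
#' cross-trait merging per protein, and — at every region where both
#' proteins harbour associated traits — the colocalisation cascade:
#' COJO secondary-signal counts, within-protein grouping (single- and
#' multi-signal pools, transitive closure, lowest-p representatives),
#' between-protein colocalisation of the representatives, PwCoCo fallback
#' when colocalisation evidence is absent and multiple signals exist, and
#' SMR/HEIDI plus bidirectional IVW MR between the representatives.
#'
#' @param config a [run_config()].
#' @return object of class `glyc_report`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  sim <- simulate(sc, n_ref = config$n_ref)
  proteins <- names(sc$proteins)
  thr <- lapply(proteins, function(p)
    significance_threshold(config$alpha, sc$proteins[[p]]$n_traits)$threshold)
  names(thr) <- proteins
  meta <- lambda <- list()
  for (p in proteins) {
    g1 <- cohort_gwas(sim$cohorts[[1]], p)
    g2 <- cohort_gwas(sim$cohorts[[2]], p)
    meta[[p]] <- lapply(names(g1), function(tr)
      meta_trait(list(g1[[tr]], g2[[tr]])))
    names(meta[[p]]) <- names(g1)
    lambda[[p]] <- vapply(meta[[p]], attr, 0, "lambda_gc")
  }
  trait_loci <- list()
  loci <- list()
  for (p in proteins) {
    tl <- do.call(rbind, lapply(meta[[p]], define_trait_loci,
                                threshold = thr[[p]]))
    trait_loci[[p]] <- tl
    loci[[p]] <- merge_loci_across_traits(tl)
  }
  all_tl <- do.call(rbind, trait_loci)
  regions <- if (!is.null(all_tl) && nrow(all_tl))
    merge_loci_across_traits(all_tl) else NULL
  region_reports <- list()
  if (!is.null(regions)) for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    in_region <- function(s)
      s$CHR == rg$chr & s$POS >= rg$start - 250000 & s$POS <= rg$end + 250000
    # traits associated in the region at the cascade threshold, per protein
    assoc <- lapply(proteins, function(p) {
      ps <- vapply(meta[[p]], function(m)
        suppressWarnings(min(m$P[in_region(m)], na.rm = TRUE)), 0)
      names(ps)[ps <= config$cascade_p]
    })
    names(assoc) <- proteins
    if (any(!vapply(assoc, length, 0L))) {
      region_reports[[ri]] <- list(region = rg, verdict = "single_protein",
                                   assoc = assoc)
      next
    }
    reg_meta <- sig <- tr_p <- models <- list()
    for (p in proteins) {
      reg_meta[[p]] <- lapply(meta[[p]][assoc[[p]]], function(m)
        m[in_region(m), , drop = FALSE])
      models[[p]] <- lapply(reg_meta[[p]], cojo_slct, ldref = sim$ldref,
                            p_threshold = config$cojo_p,
                            collinearity = config$collinearity)
      sig[[p]] <- vapply(models[[p]], function(m)
        if (is.null(m$selected)) 0L else nrow(m$selected), 0L)
      tr_p[[p]] <- vapply(reg_meta[[p]], function(m)
        suppressWarnings(min(m$P, na.rm = TRUE)), 0)
    }
    casc <- lapply(proteins, function(p)
      within_protein_cascade(reg_meta[[p]], tr_p[[p]], sig[[p]],
                             config$priors, config$pp_threshold))
    names(casc) <- proteins
    repA <- casc[[1]]$representative
    repB <- casc[[2]]$representative
    cross <- suppressWarnings(coloc_abf(reg_meta[[proteins[1]]][[repA]],
                                        reg_meta[[proteins[2]]][[repB]],
                                        config$priors))
    pw <- NULL
    if (cross$pp[["PP.H4"]] > config$pp_threshold) {
      verdict <- "colocalises"
    } else if (max(sig[[proteins[1]]][repA], sig[[proteins[2]]][repB]) > 1) {
      pw <- pwcoco(reg_meta[[proteins[1]]][[repA]],
                   reg_meta[[proteins[2]]][[repB]], sim$ldref,
                   models[[proteins[1]]][[repA]],
                   models[[proteins[2]]][[repB]],
                   config$priors, config$pp_threshold)
      verdict <- pw$verdict
    } else {
      verdict <- if (cross$pp[["PP.H3"]] > config$pp_threshold) "distinct"
      else "inconclusive"
    }
    sentA <- {
      m <- reg_meta[[proteins[1]]][[repA]]
      m$SNP[which.min(m$P)]
    }
    smr_res <- tryCatch(
      smr(reg_meta[[proteins[1]]][[repA]], reg_meta[[proteins[2]]][[repB]],
          sentA, sim$ldref),
      error = function(e) list(status = "failed", message = conditionMessage(e)))
    mr_res <- mr_bidirectional(reg_meta[[proteins[1]]][[repA]],
                               reg_meta[[proteins[2]]][[repB]], sim$ldref,
                               labels = paste(c(repA, repB), c(repB, repA),
                                              sep = " -> "))
    region_reports[[ri]] <- list(
      region = rg, assoc = assoc, n_signals = sig,
      representatives = stats::setNames(c(repA, repB), proteins),
      cascade = casc, cross_coloc = cross, pwcoco = pw,
      verdict = verdict, smr = smr_res, mr = mr_res)
  }
  structure(list(
    scenario = sc, config = config, thresholds = thr, lambda = lambda,
    loci = loci, regions = regions, region_reports = region_reports,
    meta = meta, seed = sc$seed), class = "glyc_report")
}

#' @export
print.glyc_report <- function(x, ...) {
  cat("Two-protein glycosylation comparison\n")
  for (p in names(x$loci))
    cat(sprintf("  %s: %d locus/loci at p <= %.3g (lambda_GC %.3f-%.3f)\n",
                p, nrow(x$loci[[p]]), x$thresholds[[p]],
                min(x$lambda[[p]]), max(x$lambda[[p]])))
  if (!length(x$region_reports)) {
    cat("  no significant regions; cascade skipped\n")
    return(invisible(x))
  }
  for (rr in x$region_reports) {
    cat(sprintf("  region %s:%d-%d: verdict %s", rr$region$chr,
                rr$region$start, rr$region$end, rr$verdict))
    if (!is.null(rr$representatives))
      cat(sprintf(" (representatives %s)",
                  paste(rr$representatives, collapse = " vs ")))
    cat("\n")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `loci.tsv` (per-protein merged loci), `coloc_report.json`
#' (verdicts, posterior probabilities, groups), `smr_report.json` and
#' `run.log` (seeds, thresholds, versions).
#'
#' @param report a `glyc_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- do.call(rbind, lapply(names(report$loci), function(p) {
    l <- report$loci[[p]]
    if (!nrow(l)) return(NULL)
    cbind(protein = p, l)
  }))
  if (is.null(loci)) loci <- data.frame()
  utils::write.table(loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  coloc_json <- lapply(report$region_reports, function(rr) {
    out <- list(region = sprintf("%s:%d-%d", rr$region$chr, rr$region$start,
                                 rr$region$end),
                verdict = rr$verdict, assoc = rr$assoc)
    if (!is.null(rr$cross_coloc)) {
      out$representatives <- as.list(rr$representatives)
      out$cross_pp <- as.list(rr$cross_coloc$pp)
      out$n_signals <- lapply(rr$n_signals, as.list)
    }
    if (!is.null(rr$pwcoco)) out$pwcoco <- rr$pwcoco$runs
    out
  })
  jsonlite::write_json(coloc_json, file.path(dir, "coloc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  smr_json <- lapply(report$region_reports, function(rr) {
    if (is.null(rr$smr)) return(NULL)
    s <- rr$smr
    if (inherits(s, "smr_result"))
      list(sentinel = s$sentinel, top_snp = s$top_snp, b_smr = s$b_smr,
           p_smr = s$p_smr, t_heidi = s$t_heidi, p_heidi = s$p_heidi,
           m = s$m, status = s$status,
           mr = lapply(rr$mr, function(m) if (m$status == "ok")
             list(direction = m$direction, beta = m$ivw_beta,
                  se = m$ivw_se, p = m$ivw_p,
                  n_instruments = m$n_instruments)
             else list(direction = m$direction, status = m$status)))
    else s
  })
  jsonlite::write_json(smr_json, file.path(dir, "smr_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("glycoloc %s", as.character(utils::packageVersion("glycoloc"))),
    sprintf("R %s", getRversion()),
    sprintf("timestamp %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed %d", report$seed),
    sprintf("alpha %g; cascade_p %g; cojo_p %g; pp_threshold %g",
            report$config$alpha, report$config$cascade_p,
            report$config$cojo_p, report$config$pp_threshold),
    sprintf("thresholds: %s", paste(sprintf("%s=%.3g", names(report$thresholds),
                                            unlist(report$thresholds)),
                                    collapse = ", ")),
    sprintf("verdicts: %s", paste(vapply(report$region_reports,
                                         `[[`, "", "verdict"),
                                  collapse = ", "))),
    file.path(dir, "run.log"))
  invisible(dir)
}
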