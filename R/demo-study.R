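#' Demo study configuration
#'
#' Parameters of the end-to-end synthetic demonstration study run by
#' [runDemoStudy()]. Defaults are desk-scale: large enough for the
#' pipeline's statistics to be meaningful, small enough to run in well
#' under a minute per stage.
#'
#' @param nTotal Peptides per synthetic allele study.
#' @param binderFraction Binder fraction per allele (class imbalance).
#' @param ddgNoiseSd Noise sd on the synthetic ddG profiles (kJ/mol).
#' @param motifSharpness Consensus residue probability of the generated
#'   motifs.
#' @param backgroundSize Background-set size used by the engines.
#' @param nExplain Binders explained per allele and method.
#' @param shapEvals Kernel-SHAP coalition-evaluation budget.
#' @param limeSamples LIME sample budget.
#' @param nPerm Consistency permutation-baseline size.
#' @param clusterSweeps Gibbs sweeps for the stability clustering.
#' @param maxPerCluster Stability sampling cap per cluster.
#' @return Named list of settings.
#' @export
demoConfig <- function(nTotal = 400L, binderFraction = 0.10,
                       ddgNoiseSd = 1.5, motifSharpness = 0.7,
                       backgroundSize = 20L, nExplain = 12L,
                       shapEvals = 2000L, limeSamples = 2000L,
                       nPerm = 100L, clusterSweeps = 40L,
                       maxPerCluster = 25L) {
  list(nTotal = as.integer(nTotal), binderFraction = binderFraction,
       ddgNoiseSd = ddgNoiseSd, motifSharpness = motifSharpness,
       backgroundSize = as.integer(backgroundSize),
       nExplain = as.integer(nExplain), shapEvals = as.integer(shapEvals),
       limeSamples = as.integer(limeSamples), nPerm = as.integer(nPerm),
       clusterSweeps = as.integer(clusterSweeps),
       maxPerCluster = as.integer(maxPerCluster))
}

#' Sharp motif PSSM from a consensus peptide
#'
#' Builds a PSSM giving probability \code{sharpness[p]} to the consensus
#' residue at position p and spreading the remainder uniformly over the
#' other 19 residues. A per-position sharpness vector models anchor
#' positions (near-deterministic residues, as at P2/P9 of real class I
#' motifs) against weakly constrained ones.
#'
#' @param consensus Consensus peptide.
#' @param sharpness Consensus residue probability, scalar or one value per
#'   position (default 0.7).
#' @param background Background vector recorded on the PSSM.
#' @return A \linkS4class{PSSM}.
#' @export
motifFromConsensus <- function(consensus, sharpness = 0.7,
                               background = uniformBackground()) {
  .assertPeptides(consensus, what = "consensus peptide")
  L <- nchar(consensus)
  sharpness <- rep_len(sharpness, L)
  stopifnot(all(sharpness > 0), all(sharpness <= 1))
  idx <- .pepIndex(consensus)[1L, ]
  prob <- matrix((1 - sharpness) / 19, L, 20L,
                 dimnames = list(NULL, AA_ALPHABET))
  prob[cbind(seq_len(L), idx)] <- sharpness
  PSSM(prob, background = background)
}

#' Version and provenance manifest
#'
#' @param config A [demoConfig()] list (or any named parameter list).
#' @param globalSeed The run's global seed.
#' @param seeds Named list of derived per-stage seeds.
#' @param files Character vector of report files produced.
#' @return Manifest list: tool name/version, a deterministic config hash,
#'   the global seed, per-stage seeds and output files.
#' @export
versionManifest <- function(config, globalSeed = NA_integer_,
                            seeds = list(), files = character(0)) {
  hashInput <- paste(deparse(config[order(names(config))]), collapse = "")
  list(tool = "pepXplain",
       version = as.character(packageVersion("pepXplain")),
       config_hash = deriveSeed(7L, hashInput),
       global_seed = globalSeed,
       stage_seeds = seeds,
       files = files,
       schema = "pepXplain-manifest/1")
}

#' Run the end-to-end synthetic demonstration study
#'
#' Executes the full pipeline on synthetic data: two single-allele studies
#' (distinct motifs) are generated and pooled; two surrogate predictors
#' are built (one from the true motifs, one re-estimated from the sampled
#' binders with different calibration); the pooled dataset is curated and
#' benchmarked per allele; explanations are generated with all three
#' engines; validity is scored against the synthetic ddG profiles;
#' consistency compares the two surrogates; the binders are Gibbs-
#' clustered and stability is scored over the most unrelated cluster
#' pair(s). All stage seeds derive deterministically from
#' \code{globalSeed}, so two runs with the same seed produce byte-
#' identical reports.
#'
#' @param outDir Output directory (created if missing).
#' @param globalSeed Integer global seed.
#' @param config A [demoConfig()] list.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest. Report TSVs and \code{manifest.json} are written to
#'   \code{outDir}.
#' @export
runDemoStudy <- function(outDir, globalSeed = 1L, config = demoConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  stageSeed <- function(stage) {
    seeds[[stage]] <<- deriveSeed(globalSeed, stage)
    seeds[[stage]]
  }
  files <- character(0)
  emit <- function(df, fname) {
    path <- file.path(outDir, fname)
    .writeTsv(df, path)
    files <<- c(files, fname)
    path
  }

  ## stage: simulate ---------------------------------------------------
  ## anchored motifs with different anchor positions (P2/P9 vs P3/P7),
  ## so explanation profiles genuinely differ between the two motifs
  base <- config$motifSharpness
  sharpA <- rep(0.45 * base, 9L)
  sharpA[c(2L, 9L)] <- pmin(0.97, 1.35 * base)
  sharpB <- rep(0.45 * base, 9L)
  sharpB[c(3L, 7L)] <- pmin(0.97, 1.35 * base)
  motifs <- list("HLA-A*02:01" = motifFromConsensus("YLFPGAVKV", sharpA),
                 "HLA-B*07:02" = motifFromConsensus("KPRQAYLWF", sharpB))
  studies <- lapply(seq_along(motifs), function(i) {
    makeSyntheticStudy(motifs[[i]], nTotal = config$nTotal,
                       binderFraction = config$binderFraction,
                       ddgNoiseSd = config$ddgNoiseSd,
                       seed = stageSeed(paste0("simulate_", i)),
                       allele = names(motifs)[i],
                       backgroundSize = config$backgroundSize)
  })
  names(studies) <- names(motifs)

  ## stage: predictors -------------------------------------------------
  truePssms <- motifs
  predTrue <- makePssmPredictor(truePssms, id = "surrogate_true_motif")
  estPssms <- lapply(names(motifs), function(al) {
    binders <- pepSeqs(studies[[al]]$dataset)[
      pepLabels(studies[[al]]$dataset) == 1L]
    pssmFromPeptides(binders, pseudocount = 1)
  })
  names(estPssms) <- names(motifs)
  predEst <- makePssmPredictor(estPssms, id = "surrogate_refit")

  ## stage: curate -----------------------------------------------------
  combined <- PeptideSet(
    unlist(lapply(studies, function(s) pepSeqs(s$dataset))),
    unlist(lapply(studies, function(s) pepAlleles(s$dataset))),
    label = unlist(lapply(studies, function(s) pepLabels(s$dataset))),
    name = "demo_combined")
  curated <- curateBenchmark(combined, trainingSets = list(),
                             length = pssmLength(motifs[[1L]]),
                             name = "demo_curated")
  cur <- datasetMetadata(curated)$curation
  emit(data.frame(filter = names(cur), count = unlist(cur)),
       "curation_counts.tsv")
  emit(percentBinders(curated), "percent_binders.tsv")

  ## stage: benchmark --------------------------------------------------
  preds <- list(
    surrogate_true_motif = predictBatch(predTrue, pepSeqs(curated),
                                        pepAlleles(curated)),
    surrogate_refit = predictBatch(predEst, pepSeqs(curated),
                                   pepAlleles(curated)))
  metricTable <- perAlleleMetrics(curated, preds)
  emit(metricTable, "benchmark_metrics.tsv")
  emit(topPerformerCounts(metricTable), "top_performers.tsv")

  ## stage: explain ----------------------------------------------------
  explainSeed <- stageSeed("explain")
  attrsByMethod <- list()
  attrsEstExact <- list()
  ddgAll <- list()
  for (al in names(studies)) {
    st <- studies[[al]]
    binders <- rownames(st$contributions)
    pick <- .withSeed(deriveSeed(explainSeed, al), {
      sample(binders, min(config$nExplain, length(binders)))
    })
    ddgAll <- c(ddgAll, st$ddg)
    for (pep in pick) {
      ctxSeed <- deriveSeed(explainSeed, paste0(al, pep))
      ctx <- explainContext(pep, al, predTrue, st$background,
                            seed = ctxSeed)
      attrsByMethod$exact_shapley <-
        c(attrsByMethod$exact_shapley, list(exactShapley(ctx)))
      attrsByMethod$kernel_shap <-
        c(attrsByMethod$kernel_shap,
          list(kernelShap(ctx, shapConfig(nEvaluations = config$shapEvals))))
      attrsByMethod$lime <-
        c(attrsByMethod$lime,
          list(limeExplain(ctx, limeConfig(nSamples = config$limeSamples))))
      ctxE <- explainContext(pep, al, predEst, st$background,
                             seed = ctxSeed)
      attrsEstExact <- c(attrsEstExact, list(exactShapley(ctxE)))
    }
  }
  allAttrs <- bindAttributions(c(attrsByMethod$exact_shapley,
                                 attrsByMethod$kernel_shap,
                                 attrsByMethod$lime))
  writeAttributions(allAttrs, file.path(outDir, "attributions_true.tsv"))
  files <- c(files, "attributions_true.tsv")
  writeAttributions(bindAttributions(attrsEstExact),
                    file.path(outDir, "attributions_refit.tsv"))
  files <- c(files, "attributions_refit.tsv")

  ## stage: validity ---------------------------------------------------
  vrep <- validityReport(allAttrs, ddgAll)
  emit(vrep$records, "validity_records.tsv")
  emit(vrep$summary, "validity_summary.tsv")

  ## stage: consistency ------------------------------------------------
  crep <- consistencyReport(bindAttributions(attrsByMethod$exact_shapley),
                            bindAttributions(attrsEstExact),
                            nPerm = config$nPerm,
                            seed = stageSeed("consistency"))
  emit(crep$records, "consistency_records.tsv")
  emit(data.frame(H = crep$kw$H, p_value = crep$kw$p.value,
                  effect_size = crep$kw$effectSize,
                  fraction_beating_baseline =
                    crep$fractionBeatingBaseline),
       "consistency_test.tsv")

  ## stage: cluster + stability ---------------------------------------
  allBinders <- pepSeqs(curated)[pepLabels(curated) == 1L]
  assignment <- gibbsCluster(allBinders,
                             gibbsConfig(nClusters = 2L,
                                         nSweeps = config$clusterSweeps,
                                         seed = stageSeed("cluster")))
  emit(data.frame(peptide = assignment@peptides,
                  cluster = assignment@labels),
       "clusters.tsv")
  pairs <- selectUnrelatedPairs(assignment, kPairs = 1L)
  stabSeed <- stageSeed("stability")
  clusterAttrs <- list()
  for (ci in unique(c(pairs$left, pairs$right))) {
    members <- unique(assignment@peptides[assignment@labels == ci])
    members <- .withSeed(deriveSeed(stabSeed, paste0("pick", ci)), {
      sample(members, min(config$maxPerCluster, length(members)))
    })
    for (pep in members) {
      al <- pepAlleles(curated)[match(pep, pepSeqs(curated))]
      ctx <- explainContext(pep, al, predTrue,
                            studies[[al]]$background,
                            seed = deriveSeed(stabSeed, pep))
      clusterAttrs <- c(clusterAttrs, list(exactShapley(ctx)))
    }
  }
  srep <- stabilityReport(assignment, bindAttributions(clusterAttrs),
                          clusterPairs = as.matrix(pairs[, c("left",
                                                             "right")]),
                          maxPerCluster = config$maxPerCluster,
                          seed = stabSeed)
  stabRows <- do.call(rbind, lapply(names(srep), function(nm) {
    s <- srep[[nm]]
    data.frame(pair = nm, median_intra_left = s$medians["intraL"],
               median_inter = s$medians["inter"],
               median_intra_right = s$medians["intraR"],
               kw_H = s$kw$H, kw_p = s$kw$p.value,
               effect_size = s$kw$effectSize, row.names = NULL)
  }))
  emit(stabRows, "stability.tsv")

  ## manifest ----------------------------------------------------------
  manifest <- versionManifest(config, globalSeed = globalSeed,
                              seeds = seeds, files = sort(files))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(studies = studies, curated = curated,
                 benchmark = metricTable, attributions = allAttrs,
                 validity = vrep, consistency = crep,
                 clustering = assignment, stability = srep,
                 manifest = manifest))
}
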