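test_that("peptide splicing follows the coalition mask", {
  expect_identical(perturbPeptide("AAAAAAAAA", rep(1, 9), "YYYYYYYYY"),
                   "AAAAAAAAA")
  expect_identical(perturbPeptide("AAAAAAAAA", rep(0, 9), "YYYYYYYYY"),
                   "YYYYYYYYY")
  expect_identical(perturbPeptide("AAAAAAAAA", c(1, 0, 1, 0, 1, 0, 1, 0, 1),
                                  "YYYYYYYYY"), "AYAYAYAYA")
})

test_that("coalition values reduce to prediction, baseline and single splice", {
  ctx <- randomContext(21L)
  pep <- ctx@peptide
  pred <- ctx@predictor
  L <- nchar(pep)
  expect_equal(coalitionValue(rep(1, L), ctx),
               predictBatch(pred, pep, ctx@allele))
  bg <- bgPeptides(ctx@background)
  w <- bgWeights(ctx@background)
  expect_equal(coalitionValue(rep(0, L), ctx),
               sum(w * predictBatch(pred, bg, ctx@allele)))
  single <- BackgroundSet(bg[1L])
  ctx1 <- explainContext(pep, ctx@allele, pred, single)
  mask <- c(1, 0, 0, 1, 1, 0, 1, 0, 1)
  expect_equal(coalitionValue(mask, ctx1),
               predictBatch(pred, perturbPeptide(pep, mask, bg[1L]),
                            ctx@allele))
})

test_that("exact Shapley matches an independent enumeration oracle", {
  # logistic (non-additive) surrogate, small background for oracle speed
  for (seed in c(31L, 32L)) {
    ctx <- randomContext(seed, bgK = 5L)
    phi <- attrValues(exactShapley(ctx))
    ref <- oracleShapley(ctx@peptide, ctx@allele, ctx@predictor,
                         bgPeptides(ctx@background),
                         bgWeights(ctx@background))
    expect_equal(unname(phi), ref, tolerance = 1e-9)
  }
})

test_that("exact Shapley is analytic on an additive surrogate", {
  motif <- anchoredMotif()
  pred <- makePssmPredictor(motif, link = "linear", id = "lin")
  bg <- testBackground(8L, seed = 44L)
  pep <- samplePeptidesFromPssm(motif, 1L, seed = 45L)
  ctx <- explainContext(pep, "HLA-A*02:01", pred, bg)
  phi <- attrValues(exactShapley(ctx))
  expect_equal(unname(phi),
               analyticAdditivePhi(motif, pep, bg, linearSlope(motif)),
               tolerance = 1e-10)
})

test_that("exact Shapley satisfies the dummy axiom", {
  base <- makePssmPredictor(anchoredMotif(), id = "surr")
  ig <- makeIgnoresPositionPredictor(base, 5L)
  ctx <- explainContext("YLFPGAVKV", "HLA-A*02:01", ig,
                        testBackground(6L, seed = 46L))
  expect_equal(unname(attrValues(exactShapley(ctx))[5L]), 0)
})

test_that("kernel SHAP with full enumeration reproduces exact Shapley", {
  for (seed in c(51L, 52L, 53L)) {
    ctx <- randomContext(seed, bgK = 6L)
    phi <- attrValues(kernelShap(ctx, shapConfig(sampling = "enumerate")))
    ref <- attrValues(exactShapley(ctx))
    expect_lt(max(abs(phi - ref)), 1e-6)
  }
})

test_that("sampled kernel SHAP is close, deterministic and efficient", {
  ctx <- randomContext(61L, bgK = 8L)
  cfg <- shapConfig(nEvaluations = 25000L)
  ks <- kernelShap(ctx, cfg)
  ref <- exactShapley(ctx)
  expect_lt(max(abs(attrValues(ks) - attrValues(ref))), 0.02)
  expect_identical(attrValues(kernelShap(ctx, cfg)), attrValues(ks))
  # constrained estimate satisfies efficiency
  fx <- predictBatch(ctx@predictor, ctx@peptide, ctx@allele)
  expect_lt(abs(sum(attrValues(ks)) - (fx - attrBaseline(ks))), 1e-6)
  expect_error(kernelShap(ctx, shapConfig(nEvaluations = 10L)), "2L")
})

test_that("kernel SHAP error shrinks as the evaluation budget doubles up", {
  ctx0 <- randomContext(71L, bgK = 6L)
  ref <- attrValues(exactShapley(ctx0))
  budgets <- c(500L, 4000L, 32000L)
  errs <- sapply(budgets, function(b) {
    mean(vapply(1:20, function(s) {
      ctx <- explainContext(ctx0@peptide, ctx0@allele, ctx0@predictor,
                            ctx0@background, seed = 7000L + s)
      max(abs(attrValues(kernelShap(ctx, shapConfig(nEvaluations = b))) -
                ref))
    }, 1.0))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("LIME finds the only informative position and tracks additive truth", {
  # predictor reads position 2 only
  p2only <- PredictorHandle("p2_only", function(peptide, allele) {
    ifelse(substr(peptide, 2L, 2L) == "L", 0.9, 0.1)
  }, peptideLength = 9L)
  ctx <- explainContext("YLFPGAVKV", "HLA-A*02:01", p2only,
                        testBackground(10L, seed = 81L), seed = 82L)
  phi <- attrValues(limeExplain(ctx, limeConfig(nSamples = 10000L)))
  expect_gte(abs(phi[2L]), 5 * max(abs(phi[-2L])))

  # additive surrogate: LIME coefficients correlate with exact Shapley
  motif <- anchoredMotif()
  pred <- makePssmPredictor(motif, link = "linear", id = "lin")
  bg <- testBackground(10L, seed = 83L)
  pep <- samplePeptidesFromPssm(motif, 1L, seed = 84L)
  ctxA <- explainContext(pep, "HLA-A*02:01", pred, bg, seed = 85L)
  lphi <- attrValues(limeExplain(ctxA, limeConfig(nSamples = 25000L)))
  ephi <- attrValues(exactShapley(ctxA))
  expect_gte(cor(lphi, ephi), 0.95)
  # determinism
  expect_identical(attrValues(limeExplain(ctxA,
                                          limeConfig(nSamples = 2000L))),
                   attrValues(limeExplain(ctxA,
                                          limeConfig(nSamples = 2000L))))
})

test_that("LIME returns a zero vector with a warning for a constant predictor", {
  const <- PredictorHandle("const", function(peptide, allele)
    rep(0.42, length(peptide)), peptideLength = 9L)
  ctx <- explainContext("YLFPGAVKV", "HLA-A*02:01", const,
                        testBackground(5L, seed = 86L), seed = 87L)
  expect_warning(phi <- limeExplain(ctx, limeConfig(nSamples = 500L)),
                 "constant")
  expect_true(all(abs(attrValues(phi)) <= 1e-8))
})

test_that("the three engines agree on an additive predictor up to scaling", {
  motif <- anchoredMotif()
  pred <- makePssmPredictor(motif, link = "linear", id = "lin")
  bg <- testBackground(8L, seed = 91L)
  pep <- samplePeptidesFromPssm(motif, 1L, seed = 92L)
  ctx <- explainContext(pep, "HLA-A*02:01", pred, bg, seed = 93L)
  ex <- attrValues(exactShapley(ctx))
  ks <- attrValues(kernelShap(ctx, shapConfig(sampling = "enumerate")))
  lm_ <- attrValues(limeExplain(ctx, limeConfig(nSamples = 20000L)))
  expect_equal(unname(ks), unname(ex), tolerance = 1e-6)
  expect_gte(cor(lm_, ex), 0.95)
})

test_that("exact Shapley treats exchangeable positions symmetrically", {
  # motif rows 3 and 6 identical; peptide and every background peptide carry
  # the same residue at positions 3 and 6 -> the positions are exchangeable
  prob <- pssmProb(anchoredMotif())
  prob[6L, ] <- prob[3L, ]
  motif <- PSSM(prob)
  pred <- makePssmPredictor(motif, id = "sym")
  mk <- function(p) {
    substr(p, 6L, 6L) <- substr(p, 3L, 3L)
    p
  }
  bg <- BackgroundSet(vapply(uniformPeptides(8L, seed = 94L), mk, ""))
  pep <- mk(samplePeptidesFromPssm(motif, 1L, seed = 95L))
  ctx <- explainContext(pep, "HLA-A*02:01", pred, bg)
  phi <- attrValues(exactShapley(ctx))
  expect_lt(abs(phi[3L] - phi[6L]), 1e-9)
})

test_that("the dispatch front-end stamps provenance that survives file I/O", {
  ctx <- randomContext(96L, bgK = 5L)
  out <- lapply(c("exact_shapley", "kernel_shap", "lime"), function(m) {
    explainPeptide(m, ctx, cfg = if (m == "lime")
      limeConfig(nSamples = 500L) else shapConfig(nEvaluations = 500L))
  })
  expect_true(all(vapply(out, function(a) length(a@values) == 9L, TRUE)))
  tmp <- tempfile(fileext = ".tsv")
  writeAttributions(out, tmp)
  back <- attrMeta(readAttributions(tmp))
  expect_identical(back$method, c("exact_shapley", "kernel_shap", "lime"))
  expect_identical(unique(back$predictor), predictorId(ctx@predictor))
  expect_identical(unique(back$seed), 96L)
  expect_error(explainPeptide("gradients", ctx))
})
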