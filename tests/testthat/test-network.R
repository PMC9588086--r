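test_that("merged concentration is the flow-weighted mean", {
  # the device's width-tuned rungs: 150/150 -> 1/2, 50/150 -> 1/4
  expect_equal(merge_concentration(list(stream(150, 1),
                                        stream(150, 0)))$conc, 0.5)
  expect_equal(merge_concentration(list(stream(50, 1),
                                        stream(150, 0)))$conc, 0.25)
  expect_equal(merge_concentration(list(stream(3, 0.4),
                                        stream(7, 0.4)))$conc, 0.4)
  expect_error(merge_concentration(list(stream(1, 0.5))), "at least two")
  expect_error(stream(0, 0.5), "flow")
  expect_error(stream(1, 1.5), "conc")
})

test_that("merging conserves solute mass and total flow, any order", {
  for (seed in 1:25) {
    streams <- withr::with_seed(seed, {
      n <- sample(2:6, 1)
      lapply(seq_len(n), function(i) stream(runif(1, 0.1, 5), runif(1)))
    })
    out <- merge_concentration(streams)
    q <- vapply(streams, `[[`, numeric(1), "flow")
    ci <- vapply(streams, `[[`, numeric(1), "conc")
    expect_equal(out$flow, sum(q), tolerance = 1e-12)
    expect_equal(out$flow * out$conc, sum(q * ci), tolerance = 1e-12)
    # permutation invariance
    perm <- withr::with_seed(seed + 50, sample(seq_along(streams)))
    expect_equal(merge_concentration(streams[perm])$conc, out$conc,
                 tolerance = 1e-15)
    # convexity: output within the inlet concentration hull
    expect_gte(out$conc, min(ci))
    expect_lte(out$conc, max(ci))
  }
})

test_that("rectangular duct resistance matches its limiting cases", {
  mu <- 1.01e-3
  # R proportional to L
  expect_equal(rectangular_resistance(150e-6, 50e-6, 2e-3, mu),
               2 * rectangular_resistance(150e-6, 50e-6, 1e-3, mu),
               tolerance = 1e-12)
  # wide-channel limit -> parallel plates 12 mu L / (w h^3)
  w <- 100 * 50e-6; h <- 50e-6; L <- 1e-3
  expect_equal(rectangular_resistance(w, h, L, mu),
               12 * mu * L / (w * h^3), tolerance = 0.01)
  # square duct: tabulated factor 28.45 mu L / h^4
  expect_equal(rectangular_resistance(h, h, L, mu, n_terms = 10),
               28.45 * mu * L / h^4, tolerance = 0.01)
  # monotone decreasing in both dimensions; orientation-invariant
  expect_gt(rectangular_resistance(100e-6, 50e-6, L, mu),
            rectangular_resistance(150e-6, 50e-6, L, mu))
  expect_gt(rectangular_resistance(150e-6, 40e-6, L, mu),
            rectangular_resistance(150e-6, 50e-6, L, mu))
  expect_equal(rectangular_resistance(150e-6, 50e-6, L, mu),
               rectangular_resistance(50e-6, 150e-6, L, mu))
  expect_error(rectangular_resistance(0, 1e-5, 1e-3), "width")
})

test_that("the width-tuned network predicts the 1 : 1/2 : 1/4 : 0 ladder", {
  fr <- ladder_fractions(width_ladder_network())
  expect_identical(unname(fr), c(1, 0.5, 0.25, 0))
  expect_named(fr, c("dye", "B", "C", "buffer"))
})

test_that("ladder_fractions handles pass-through, convexity and bad configs", {
  passthrough <- list(inlets = list(a = 1.0, b = 0.0),
                      stages = list(),
                      outputs = c("a", "b"))
  expect_identical(unname(ladder_fractions(passthrough)), c(1, 0))
  # equal-weight random acyclic networks stay inside [0, 1]
  for (seed in 1:10) {
    net <- withr::with_seed(seed, {
      stages <- list()
      sources <- c("a", "b")
      for (k in 1:4) {
        nm <- paste0("s", k)
        pickv <- sample(sources, 2)
        stages[[nm]] <- list(list(weight = 1, source = pickv[1]),
                             list(weight = 1, source = pickv[2]))
        sources <- c(sources, nm)
      }
      list(inlets = list(a = 1.0, b = 0.0), stages = stages,
           outputs = sources)
    })
    fr <- ladder_fractions(net)
    expect_true(all(fr >= 0 & fr <= 1))
  }
  dangling <- list(inlets = list(a = 1.0),
                   stages = list(s = list(list(weight = 1, source = "nope"),
                                          list(weight = 1, source = "a"))),
                   outputs = "s")
  expect_error(ladder_fractions(dangling), "unknown source")
  expect_error(ladder_fractions(list(inlets = list(a = 1))), "stages")
})
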