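avlt_row <- function(t = c(10, 10, 10, 10, 10), b = 5, imm = 9, del = 6,
                     rec = 12, id = "s1") {
  data.frame(id = id, avlt_t1 = t[1], avlt_t2 = t[2], avlt_t3 = t[3],
             avlt_t4 = t[4], avlt_t5 = t[5], avlt_b = b, avlt_imm = imm,
             avlt_del = del, avlt_rec = rec)
}

test_that("memory components follow their definitions", {
  cp <- derive_components(avlt_row())
  expect_equal(cp$learning, 50)
  expect_equal(cp$delayed_pct, 100 * 6 / 15)
  expect_equal(cp$recognition_pct, 80)
  expect_equal(cp$gain, 80 - 40)  # recognition% minus delayed%

  # equal delayed and recognition: no gain
  cp0 <- derive_components(avlt_row(del = 6, rec = 6))
  expect_equal(cp0$gain, 0)

  # gain is antisymmetric under swapping delayed and recognition
  cp1 <- derive_components(avlt_row(del = 12, rec = 6))
  cp2 <- derive_components(avlt_row(del = 6, rec = 12))
  expect_equal(cp1$gain, -cp2$gain)

  # missing item only hits dependent components
  cpna <- derive_components(avlt_row(t = c(10, NA, 10, 10, 10)))
  expect_true(is.na(cpna$learning))
  expect_equal(cpna$delayed, 6)

  expect_error(derive_components(avlt_row(rec = 16)), "0-15")
})

test_that("reference norms use the n-1 denominator and reject degenerate data", {
  ref <- data.frame(learning = c(40, 50, 60))
  nm <- fit_norms(ref, components = "learning")
  expect_equal(nm$mean, 50)
  expect_equal(nm$sd, 10)
  expect_error(fit_norms(data.frame(learning = c(50, 50, 50)),
                         components = "learning"), "zero variance")
  expect_error(fit_norms(data.frame(learning = 50), components = "learning"),
               ">= 2")
})

test_that("impairment flags are inclusive at the boundary and direction-aware", {
  ref <- data.frame(learning = c(40, 50, 60), gain = c(-10, 0, 10))
  nm <- fit_norms(ref, components = c("learning", "gain"))
  # z = 0: not impaired; z = -1.5 exactly: impaired
  fl <- classify_impairment(data.frame(learning = c(50, 35), gain = c(0, 0)),
                            nm)
  expect_equal(fl$learning, c(FALSE, TRUE))
  # gain is flagged on the high side (high gain = retrieval problems)
  flg <- classify_impairment(data.frame(learning = 50, gain = c(15, -15)), nm)
  expect_equal(flg$gain, c(TRUE, FALSE))
})

test_that("impairment rate matches the normal tail and is monotone in the cutoff", {
  set.seed(21)
  ref <- data.frame(delayed = rnorm(5e4))
  nm <- fit_norms(ref, components = "delayed")
  x <- data.frame(delayed = rnorm(1e5))
  rate <- mean(classify_impairment(x, nm)$delayed)
  expect_lt(abs(rate - pnorm(-1.5)), 0.005)
  rate2 <- mean(classify_impairment(x, nm, threshold = 2)$delayed)
  expect_lt(rate2, rate)
})

test_that("impairment table reports percentages over non-missing denominators", {
  ref <- data.frame(learning = rnorm(100, 50, 10), delayed = rnorm(100, 9, 3))
  nm <- fit_norms(ref, components = c("learning", "delayed"))
  comp <- data.frame(id = paste0("p", 1:8),
                     learning = rep(50, 8), delayed = rep(9, 8))
  labels <- data.frame(id = comp$id,
                       subtype = factor(rep(subtype_levels(), each = 2),
                                        levels = subtype_levels()))
  tab <- impairment_table(comp, labels, nm,
                          components_use = c("learning", "delayed"))
  expect_true(all(tab$pct_typical == 0))

  comp2 <- comp
  comp2$learning <- nm$mean[nm$component == "learning"] -
    2 * nm$sd[nm$component == "learning"]
  tab2 <- impairment_table(comp2, labels, nm,
                           components_use = c("learning", "delayed"))
  expect_true(all(tab2[tab2$component == "learning",
                       paste0("pct_", subtype_levels())] == 100))

  # empty cell is NA with zero denominator
  tab3 <- impairment_table(comp[1:2, ], labels[1:2, ], nm,
                           components_use = c("learning", "delayed"))
  expect_true(is.na(tab3$pct_no_atrophy[1]))
  expect_equal(tab3$n_no_atrophy[1], 0)
})

test_that("a selective group deficit shows up only in its component", {
  set.seed(31)
  n <- 120
  ref <- data.frame(learning = rnorm(500, 50, 10), delayed = rnorm(500, 9, 3))
  nm <- fit_norms(ref, components = c("learning", "delayed"))
  comp <- data.frame(
    id = paste0("p", 1:(2 * n)),
    learning = c(rnorm(n, 30, 10), rnorm(n, 50, 10)),  # -2 SD shift, group 1
    delayed = rnorm(2 * n, 9, 3)
  )
  labels <- data.frame(id = comp$id,
                       subtype = factor(rep(c("typical", "no_atrophy"),
                                            each = n),
                                        levels = subtype_levels()))
  tab <- impairment_table(comp, labels, nm,
                          components_use = c("learning", "delayed"))
  expect_gt(tab$pct_typical[tab$component == "learning"],
            tab$pct_typical[tab$component == "delayed"] + 30)
})

test_that("split-plot interaction holds its nominal type-I rate under the null", {
  set.seed(77)
  n_sim <- 500
  rej <- logical(n_sim)
  ref <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  nm <- fit_norms(ref, components = c("a", "b", "c"))
  for (s in seq_len(n_sim)) {
    comp <- data.frame(id = paste0("p", 1:48), a = rnorm(48), b = rnorm(48),
                       c = rnorm(48))
    groups <- data.frame(id = comp$id, group = rep(c("g1", "g2", "g3", "g4"),
                                                   each = 12))
    res <- component_by_group_anova(comp, groups, nm,
                                    components_use = c("a", "b", "c"))
    rej[s] <- res$interaction$p <= 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("a single-component group shift drives the interaction", {
  set.seed(78)
  n <- 80
  ref <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  nm <- fit_norms(ref, components = c("a", "b", "c"))
  comp <- data.frame(id = paste0("p", 1:(2 * n)),
                     a = c(rnorm(n, -1.2), rnorm(n)), b = rnorm(2 * n),
                     c = rnorm(2 * n))
  groups <- data.frame(id = comp$id, group = rep(c("g1", "g2"), each = n))
  res <- component_by_group_anova(comp, groups, nm,
                                  components_use = c("a", "b", "c"))
  expect_lt(res$interaction$p, 0.001)
  # the post-hoc family localizes the effect to component a
  ph <- res$posthoc
  expect_lt(ph$p_adj[ph$component == "a"], 0.01)
  expect_true(all(ph$p_adj >= ph$p, na.rm = TRUE))
})

test_that("single-group input is rejected and rescaling a component is inert", {
  ref <- data.frame(a = rnorm(300), b = rnorm(300))
  nm <- fit_norms(ref, components = c("a", "b"))
  comp <- data.frame(id = paste0("p", 1:20), a = rnorm(20), b = rnorm(20))
  groups1 <- data.frame(id = comp$id, group = "only")
  expect_error(component_by_group_anova(comp, groups1, nm,
                                        components_use = c("a", "b")),
               ">= 2 groups")

  groups <- data.frame(id = comp$id, group = rep(c("g1", "g2"), each = 10))
  res1 <- component_by_group_anova(comp, groups, nm,
                                   components_use = c("a", "b"))
  # affine rescaling of one component, applied to data and reference alike,
  # cannot change the standardized analysis
  ref2 <- ref; ref2$a <- 7 + 3 * ref2$a
  comp2 <- comp; comp2$a <- 7 + 3 * comp2$a
  nm2 <- fit_norms(ref2, components = c("a", "b"))
  res2 <- component_by_group_anova(comp2, groups, nm2,
                                   components_use = c("a", "b"))
  expect_equal(res1$interaction$F, res2$interaction$F, tolerance = 1e-10)
})
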