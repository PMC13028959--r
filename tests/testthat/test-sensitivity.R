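test_that("parameters without a pathway to a readout score zero", {
  base <- ref_scenario(t_end_h = 48, output_dt_h = 0.25)
  S <- local_sensitivity(base, parameters = c("drug.k_feces", "pd.RTG0"),
                         delta = 0.01)
  # fecal transit speed touches no plasma or urine readout
  expect_equal(unname(S["drug.k_feces", c("AUC_DAP", "Cmax_DAP", "AUC_D3G",
                                          "UGE24")]),
               rep(0, 4), tolerance = 1e-6)
  # baseline threshold does not affect PK
  expect_lt(abs(S["pd.RTG0", "AUC_DAP"]), 1e-6)
  # ... but strongly affects glucosuria
  expect_lt(S["pd.RTG0", "UGE24"], -0.5)
})

test_that("sensitivity signs match pharmacology", {
  base <- ref_scenario(t_end_h = 48, output_dt_h = 0.25)
  S <- local_sensitivity(base,
                         parameters = c("drug.ka", "drug.k_DAPEX_ki",
                                        "drug.Vmax_li", "drug.f_ki_Vmax"))
  expect_gt(S["drug.ka", "Cmax_DAP"], 0)
  expect_lt(S["drug.k_DAPEX_ki", "AUC_DAP"], 0)
  expect_lt(S["drug.f_ki_Vmax", "AUC_DAP"], 0)
  expect_gt(S["drug.f_ki_Vmax", "AUC_D3G"], 0)
})

test_that("midpoint sensitivities are step-size robust", {
  base <- ref_scenario(t_end_h = 48, output_dt_h = 0.25)
  s1 <- local_sensitivity(base, parameters = "drug.ka", delta = 0.01)
  s2 <- local_sensitivity(base, parameters = "drug.ka", delta = 0.005)
  expect_equal(s1["drug.ka", "AUC_DAP"], s2["drug.ka", "AUC_DAP"],
               tolerance = 1e-3)
  expect_equal(s1["drug.ka", "Cmax_DAP"], s2["drug.ka", "Cmax_DAP"],
               tolerance = 1e-3)
})

test_that("filtering drops flat rows and clustering orders the rest", {
  S <- structure(matrix(c(0.01, -0.02, 0.05,
                          0.5, 0.5, 0.5,
                          0.5, 0.5, 0.5), nrow = 3, byrow = TRUE,
                        dimnames = list(c("flat", "dup1", "dup2"),
                                        c("a", "b", "c"))),
                 class = c("sensitivity_matrix", "matrix", "array"),
                 perturbation = 0.01)
  out <- filter_and_cluster(S, threshold = 0.1)
  expect_equal(nrow(out), 2)
  expect_setequal(rownames(out), c("dup1", "dup2"))  # identical rows adjacent
  expect_warning(filter_and_cluster(S, threshold = 10), "empty")
})

test_that("single-linkage merge order matches the hand-computed dendrogram", {
  # rows at mutual distances d(A,B)=1, d(B,C)=2, d(A,C)=3:
  # single linkage merges {A,B} at height 1, then C at height 2
  S <- structure(matrix(c(0, 1, 3), ncol = 1,
                        dimnames = list(c("A", "B", "C"), "q")),
                 class = c("sensitivity_matrix", "matrix", "array"),
                 perturbation = 0.01)
  out <- filter_and_cluster(S, threshold = 0)
  hc <- attr(out, "clustering")
  expect_equal(hc$height, c(1, 2))
  expect_setequal(hc$merge[1, ], c(-1, -2))  # A and B merge first
  expect_equal(rownames(out), c("A", "B", "C")[hc$order])
})
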