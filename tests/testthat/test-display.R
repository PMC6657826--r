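win <- function(starts, allele = "A*0101") {
  tibble::tibble(protein_id = "P1", allele = allele, start = as.integer(starts),
                 affinity = 10)
}

test_that("panel mask covers 9-mer windows and their unions", {
  expect_true(all(build_panel_mask(9L, win(1))))
  m <- build_panel_mask(20L, win(c(1, 12)))
  expect_true(all(m[c(1:9, 12:20)]))
  expect_false(any(m[10:11]))
  # overlapping windows
  m2 <- build_panel_mask(15L, win(c(1, 5)))
  expect_equal(which(m2), 1:13)
})

test_that("out-of-bounds windows are an error", {
  expect_error(build_panel_mask(20L, win(13)), "out of bounds",
               class = "nd_data_error")
  expect_silent(build_panel_mask(20L, win(12)))
})

test_that("panel mask equals the per-allele OR (union property)", {
  set.seed(21)
  panel <- default_hla_panel()$allele
  for (i in 1:20) {
    L <- sample(9:80, 1)
    n <- sample(0:10, 1)
    w <- tibble::tibble(
      protein_id = "P1",
      allele = sample(panel, n, TRUE),
      start = sample(seq_len(L - 8L), n, TRUE),
      affinity = 10
    )
    M <- allele_mask_matrix(L, w, panel)
    expect_equal(build_panel_mask(L, w), rowSums(M) > 0)
  }
})

test_that("patient copy counts follow genotype copies of displaying alleles", {
  L <- 30L
  w <- win(5, "A*0201")
  M <- allele_mask_matrix(L, w, default_hla_panel()$allele)
  # homozygous displaying allele -> copy count 2 on covered residues (D2)
  cc_hom <- build_patient_mask(M, c("A*0201" = 2L, "B*0702" = 2L))
  expect_equal(cc_hom[5:13], rep(2L, 9))
  expect_equal(cc_hom[1:4], rep(0L, 4))
  # heterozygous, one displaying allele -> D1
  cc_het <- build_patient_mask(M, c("A*0201" = 1L, "A*0101" = 1L))
  expect_equal(cc_het[5:13], rep(1L, 9))
  # two distinct displaying alleles -> D2
  w2 <- dplyr::bind_rows(win(5, "A*0201"), win(7, "B*0702"))
  M2 <- allele_mask_matrix(L, w2, default_hla_panel()$allele)
  cc2 <- build_patient_mask(M2, c("A*0201" = 1L, "B*0702" = 1L))
  expect_equal(cc2[7:13], rep(2L, 7))
  # carried allele without predictions contributes nothing
  cc_ext <- build_patient_mask(M, c("A*1101" = 2L))
  expect_true(all(cc_ext == 0L))
})

test_that("site classification distinguishes OUT, D0, D1, D2", {
  L <- 20L
  w <- dplyr::bind_rows(win(1, "A*0101"), win(12, "B*0702"))
  M <- allele_mask_matrix(L, w, default_hla_panel()$allele)
  pan <- build_panel_mask(L, w)
  expect_equal(classify_site(10L, pan), "OUT")
  expect_equal(classify_site(5L, pan), "IN")
  # patient carries B*0702 only: positions 1..9 displayed only by a
  # non-carried panel allele -> D0 (excluded downstream)
  cc <- build_patient_mask(M, c("B*0702" = 1L))
  expect_equal(classify_site(5L, pan, cc), "D0")
  expect_equal(classify_site(15L, pan, cc), "D1")
  expect_equal(classify_site(10L, pan, cc), "OUT")
  # copy count 3 collapses to D2
  cc3 <- build_patient_mask(M, c("A*0101" = 2L, "B*0702" = 1L))
  w3 <- dplyr::bind_rows(win(1, "A*0101"), win(1, "B*0702"))
  M3 <- allele_mask_matrix(L, w3, default_hla_panel()$allele)
  cc3 <- build_patient_mask(M3, c("A*0101" = 2L, "B*0702" = 1L))
  expect_equal(cc3[3], 3L)
  expect_equal(classify_site(3L, build_panel_mask(L, w3), cc3), "D2")
  expect_error(classify_site(21L, pan), "position", class = "nd_data_error")
})

test_that("adding windows or alleles never shrinks display (monotonicity)", {
  set.seed(31)
  panel <- default_hla_panel()$allele
  for (i in 1:10) {
    L <- sample(20:60, 1)
    w1 <- tibble::tibble(protein_id = "P1",
                         allele = sample(panel, 4, TRUE),
                         start = sample(seq_len(L - 8L), 4, TRUE), affinity = 10)
    extra <- tibble::tibble(protein_id = "P1", allele = sample(panel, 1),
                            start = sample(seq_len(L - 8L), 1), affinity = 10)
    m1 <- build_panel_mask(L, w1)
    m2 <- build_panel_mask(L, dplyr::bind_rows(w1, extra))
    expect_true(all(m2 >= m1))
    M <- allele_mask_matrix(L, w1, panel)
    cc1 <- build_patient_mask(M, c("A*0101" = 1L))
    cc2 <- build_patient_mask(M, c("A*0101" = 1L, "B*0702" = 1L))
    expect_true(all(cc2 >= cc1))
  }
})

test_that("patient-mode classes partition every residue", {
  set.seed(41)
  panel <- default_hla_panel()$allele
  for (i in 1:10) {
    L <- sample(20:60, 1)
    n <- sample(1:8, 1)
    w <- tibble::tibble(protein_id = "P1", allele = sample(panel, n, TRUE),
                        start = sample(seq_len(L - 8L), n, TRUE), affinity = 10)
    M <- allele_mask_matrix(L, w, panel)
    cc <- build_patient_mask(M, c("A*0201" = 1L, "B*0801" = 2L))
    pan <- build_panel_mask(L, w)
    cls <- classify_site(seq_len(L), pan, cc)
    expect_true(all(cls %in% c("OUT", "D0", "D1", "D2")))
    expect_equal(length(cls), L)
  }
})

test_that("BED export uses 0-based half-open runs in deterministic order", {
  cls <- c("OUT", "OUT", "D1", "D1", "D1", "OUT", "D2")
  bed <- mask_to_bed("P1", cls)
  expect_equal(bed$start, c(0L, 2L, 5L, 6L))
  expect_equal(bed$end, c(2L, 5L, 6L, 7L))
  expect_equal(bed$class, c("OUT", "D1", "OUT", "D2"))
  expect_equal(sum(bed$end - bed$start), length(cls))
})
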