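test_that("rounded average masses reproduce the designed-peptide table", {
  expected <- c(pep1 = 1779L, pep2 = 1493L, pep3 = 1222L, pep6 = 1451L,
                pep7 = 1449L, pep8 = 1488L, pep9 = 1014L)
  for (nm in names(expected))
    expect_identical(peptide_mass(parse_peptide(table2_specs[[nm]]))$rounded,
                     expected[[nm]], label = nm)
})

test_that("single glycine with free termini weighs one residue plus water", {
  expect_equal(peptide_mass(parse_peptide("G"))$mass, 57.0519 + 18.0153,
               tolerance = 1e-10)
})

test_that("parse_peptide handles termini, staples and bad input", {
  p <- parse_peptide("Ac-GGRRGLVCGV-NH2")
  expect_s3_class(p, "peptide")
  expect_equal(p$sequence, "GGRRGLVCGV")
  expect_equal(p$n_term, "acetyl")
  expect_equal(p$c_term, "amide")

  bare <- parse_peptide("G")
  expect_equal(c(bare$n_term, bare$c_term), c("free", "free"))

  st <- parse_peptide("Ac-RKEYLEELDGGR-NH2 staple=2,6")
  expect_equal(st$staple, c(2L, 6L))

  expect_error(parse_peptide("Ac-GGXRG-NH2"), "unknown residue")
  expect_error(parse_peptide("Ac-GKREG-NH2 staple=2"), "malformed staple")
  expect_error(parse_peptide("Ac-GGRRG-NH2 staple=1,2"), "incompatible")
  expect_error(parse_peptide("Ac-GKREG-NH2 staple=2,2"), "distinct")
})

test_that("parse/format round-trips the dialect", {
  specs <- c("Ac-GGRRGLVCGV-NH2", "GGR", "Ac-YLMELD", "YLMELD-NH2",
             "Ac-RKEYLEELDGGR-NH2 staple=2,6")
  for (s in specs)
    expect_identical(format_peptide(parse_peptide(s)), s)
  # and the other direction on random peptides
  set.seed(42)
  aa <- names(mass_table()$residues)
  for (i in 1:25) {
    p <- peptide(paste(sample(aa, sample(5:20, 1), replace = TRUE),
                       collapse = ""),
                 n_term = sample(c("free", "acetyl"), 1),
                 c_term = sample(c("free", "amide"), 1))
    q <- parse_peptide(format_peptide(p))
    expect_identical(q[c("sequence", "n_term", "c_term")],
                     p[c("sequence", "n_term", "c_term")])
  }
})

test_that("mass is additive over concatenation (free termini)", {
  set.seed(7)
  aa <- names(mass_table()$residues)
  w <- mass_table()$water
  for (i in 1:20) {
    a <- paste(sample(aa, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:12, 1), TRUE), collapse = "")
    expect_equal(peptide_mass(peptide(paste0(a, b)))$mass,
                 peptide_mass(peptide(a))$mass + peptide_mass(peptide(b))$mass - w,
                 tolerance = 1e-9)
  }
})

test_that("alanine scan generates the designed substitution variants", {
  p2 <- parse_peptide(table2_specs[["pep2"]], label = "pep2")
  variants <- alanine_scan(p2, c(4, 7, 8, 9))
  expect_length(variants, 4)
  expect_equal(vapply(variants, `[[`, character(1), "sequence"),
               vapply(table2_specs[c("pep4", "pep5", "pep6", "pep7")],
                      function(s) parse_peptide(s)$sequence, character(1),
                      USE.NAMES = FALSE))
  # termini propagate
  expect_true(all(vapply(variants, `[[`, character(1), "n_term") == "acetyl"))
  # scanning an existing alanine is idempotent on the sequence
  pA <- peptide("GAG")
  expect_equal(alanine_scan(pA, 2)[[1]]$sequence, "GAG")
  expect_error(alanine_scan(pA, 9), "out of range")
})

test_that("fragments slice the parent with capped termini", {
  p1 <- parse_peptide(table2_specs[["pep1"]])
  expect_equal(peptide_fragment(p1, 7, 16)$sequence, "GGRRGLVCGV")
  expect_equal(peptide_fragment(p1, 1, 10)$sequence, "YLMELDGGRR")
  full <- peptide_fragment(p1, 1, nchar(p1$sequence))
  expect_identical(full$sequence, p1$sequence)
  expect_equal(full$n_term, "acetyl")
  expect_error(peptide_fragment(p1, 10, 7), "inverted")
  expect_error(peptide_fragment(p1, 0, 5), "out of range|inverted")
})

test_that("stapling substitutes a lactam pair and loses one water", {
  p2 <- parse_peptide(table2_specs[["pep2"]])
  st <- peptide_staple(p2, 2, 6)  # L2K, M6E
  expect_equal(st$sequence, "RKEYLEELDGGR")
  expect_equal(st$staple, c(2L, 6L))
  linear <- peptide(st$sequence, n_term = st$n_term, c_term = st$c_term)
  expect_equal(peptide_mass(st)$mass - peptide_mass(linear)$mass, -18.0153,
               tolerance = 1e-9)
  expect_error(peptide_staple(p2, 2, 2), "distinct")
  expect_error(peptide_staple(p2, 2, 6, sub_i = "K", sub_j = "K"),
               "invalid lactam pair")
})

test_that("peptide_table tabulates rounded MWs and validates labels", {
  tab <- peptide_table(unname(table2_specs), labels = names(table2_specs))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$mw_da[tab$label == "pep1"], 1779L)
  expect_equal(tab$mw_da[tab$label == "pep9"], 1014L)
  expect_error(peptide_table(c("G", "G"), labels = c("a", "a")), "duplicate")
  expect_error(peptide_table("Ac-GXG-NH2"), "row 1")
  empty <- peptide_table(character(0))
  expect_equal(nrow(empty), 0)
  tf <- tempfile(fileext = ".tsv")
  peptide_table(unname(table2_specs), labels = names(table2_specs), file = tf)
  back <- read.delim(tf)
  expect_equal(back$mw_da, tab$mw_da)
  unlink(tf)
})
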