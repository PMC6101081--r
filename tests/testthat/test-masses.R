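test_that("residue masses agree with atomic-composition arithmetic", {
  # independent oracle: monoisotopic atomic masses summed by hand-written
  # compositions
  el <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
          S = 31.97207100)
  oracle <- c(
    G = 2 * el["C"] + 3 * el["H"] + el["N"] + el["O"],
    K = 6 * el["C"] + 12 * el["H"] + 2 * el["N"] + el["O"],
    R = 6 * el["C"] + 12 * el["H"] + 4 * el["N"] + el["O"],
    S = 3 * el["C"] + 5 * el["H"] + el["N"] + 2 * el["O"],
    W = 11 * el["C"] + 10 * el["H"] + 2 * el["N"] + el["O"])
  expect_equal(residue_mass(c("G", "K", "R", "S", "W")), unname(oracle),
               tolerance = 1e-10)
  # frozen published values to 5 decimals
  expect_equal(residue_mass("G"), 57.02146, tolerance = 1e-5)
  expect_equal(residue_mass("K"), 128.09496, tolerance = 1e-5)
  expect_error(residue_mass("B"), "B")
  expect_error(prefix_residue_masses("GKXZ"), "X")
})

test_that("prefix residue masses start at zero and imply the suffix masses", {
  expect_identical(prefix_residue_masses(""), 0)
  expect_equal(prefix_residue_masses("GG"), c(0, 57.02146, 114.04293),
               tolerance = 1e-5)
  set.seed(42)
  for (i in 1:5) {
    s <- random_modifiable_seq(sample(3:10, 1))
    p <- prefix_residue_masses(s)
    n <- nchar(s)
    expect_length(p, n + 1L)
    expect_true(all(diff(p) > 0))
    chars <- strsplit(s, "")[[1]]
    suffix <- vapply(0:n, function(i) {
      if (i == 0) 0 else sum(residue_mass(chars[(n - i + 1):n]))
    }, numeric(1))
    expect_equal(p[n + 1L] - rev(p), suffix)
  }
})

test_that("proteoform masses add water and PTM shifts", {
  pt <- default_ptm_table()
  pf0 <- proteoform("AKGKL")
  p <- prefix_residue_masses("AKGKL")
  expect_equal(proteoform_mass(pf0), p[6] + WATER_MONO)
  pf_ac <- proteoform("AKGKL", data.frame(position = 2, name = "Acetylation"), pt)
  expect_equal(proteoform_mass(pf_ac), proteoform_mass(pf0) + 42.01056)
  pf_two <- proteoform("SKGKL", data.frame(position = c(1, 2),
                                           name = c("Phosphorylation", "Acetylation")),
                       pt)
  expect_equal(proteoform_mass(pf_two),
               proteoform_mass(proteoform("SKGKL")) + 42.01056 + 79.96633)
})

test_that("proteoform validation rejects bad modifications", {
  pt <- default_ptm_table()
  expect_error(proteoform("AKGKL", data.frame(position = 9, name = "Acetylation"), pt),
               "position")
  expect_error(proteoform("AKGKL", data.frame(position = 1, name = "Acetylation"), pt),
               "not allowed")
  expect_error(proteoform("AKGKL", data.frame(position = c(2, 2),
                                              name = c("Acetylation", "Methylation")),
                          pt),
               "one PTM per residue")
  expect_error(proteoform("AKGKL", data.frame(position = 2, name = "Sumoylation"), pt),
               "Sumoylation")
})

test_that("proteoform strings round-trip through parse and format", {
  pt <- default_ptm_table()
  for (s in c("GK[Acetylation]GK[Acetylation]LKAKE",
              "GKGK[Acetylation]LK[Trimethylation]AKE",  # invalid residue caught below
              "AKGKL")) {
    if (grepl("Trimethylation", s)) {
      expect_error(parse_proteoform(s, pt), "not allowed")  # Trimethylation is R-only
    } else {
      expect_identical(format(parse_proteoform(s, pt)), s)
    }
  }
})

test_that("PTM tables read identically from TSV and YAML", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tmonoisotopic_mass\tresidues",
               "Acetylation\t42.01056\tR,K",
               "Phosphorylation\t79.96633\tS,T,Y"), tsv)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("- name: Acetylation", "  monoisotopic_mass: 42.01056",
               "  residues: [R, K]",
               "- name: Phosphorylation", "  monoisotopic_mass: 79.96633",
               "  residues: [S, T, Y]"), yml)
  a <- read_ptm_table(tsv)
  b <- read_ptm_table(yml)
  expect_equal(a$name, b$name)
  expect_equal(a$mass_shift, b$mass_shift)
  expect_equal(lapply(a$residues, function(r) sort(strsplit(r, ",")[[1]])),
               lapply(b$residues, function(r) sort(strsplit(r, ",")[[1]])))
  # packaged default covers the five histone PTMs with trimethylation on R only
  def <- default_ptm_table()
  expect_identical(nrow(def), 5L)
  expect_identical(def$residues[def$name == "Trimethylation"], "R")
})

test_that("acetylation-only enumeration of AKGKL matches the hand-enumerated sets", {
  pt <- default_ptm_table()[default_ptm_table()$name == "Acetylation", ]
  q <- enumerate_proteoforms("AKGKL", pt)
  expect_length(q, 3L)
  expect_setequal(vapply(q, format, character(1)),
                  c("AK[Acetylation]GKL", "AKGK[Acetylation]L",
                    "AK[Acetylation]GK[Acetylation]L"))
  m1 <- proteoform_mass(proteoform("AKGKL")) + 42.01056
  qm <- enumerate_proteoforms("AKGKL", pt, precursor_mass = m1)
  expect_setequal(vapply(qm, format, character(1)),
                  c("AK[Acetylation]GKL", "AKGK[Acetylation]L"))
  pms <- enumerate_prefix_mass_sets("AKGKL", pt, precursor_mass = m1)
  p <- prefix_residue_masses("AKGKL")
  expect_equal(pms$sets[[3]], c(p[3], p[3] + 42.01056), tolerance = 1e-9)
  expect_equal(pms$sets[[5]], p[5] + 42.01056, tolerance = 1e-9)
  expect_equal(pms$sets[[1]], 0)
})

test_that("an unmodified precursor at zero tolerance forces the bare prefix masses", {
  m0 <- proteoform_mass(proteoform(EXAMPLE_SEQ))
  pms <- enumerate_prefix_mass_sets(EXAMPLE_SEQ, default_ptm_table(),
                                    precursor_mass = m0, precursor_tol_ppm = 0)
  expect_equal(unlist(pms$sets), prefix_residue_masses(EXAMPLE_SEQ))
})

test_that("prefix-mass sets agree with brute-force proteoform enumeration", {
  full <- default_ptm_table()
  pt <- full[full$name %in% c("Acetylation", "Phosphorylation"), ]
  set.seed(11)
  tested <- 0L
  for (rep in 1:12) {
    s <- random_modifiable_seq(sample(4:8, 1))
    all_pf <- enumerate_proteoforms(s, pt, include_unmodified = TRUE)
    if (length(all_pf) < 2L) next
    target <- all_pf[[sample(length(all_pf), 1)]]
    M <- proteoform_mass(target)
    tol <- 5
    qm <- Filter(function(pf) abs(proteoform_mass(pf) - M) <= tol * 1e-6 * M, all_pf)
    pms <- enumerate_prefix_mass_sets(s, pt, precursor_mass = M,
                                      precursor_tol_ppm = tol)
    # oracle: the distinct i-th prefix masses over proteoforms matching M
    for (i in seq_len(nchar(s) + 1L)) {
      oracle <- sort(unique(round(vapply(qm, function(pf) {
        proteoform_prefix_masses(pf)[i]
      }, numeric(1)), 5)))
      expect_equal(round(pms$sets[[i]], 5), oracle)
    }
    # connectivity: every mass in P_{i+1} has a preceding mass in P_i
    for (i in seq_len(nchar(s))) {
      d2 <- pms$shift_sets[[i + 1L]]
      d1 <- pms$shift_sets[[i]]
      steps <- c(0, pt$mass_shift[vapply(pt$residues, function(r) {
        substr(s, i, i) %in% strsplit(r, ",")[[1]]
      }, logical(1))])
      for (m2 in d2) {
        expect_true(any(outer(d1, steps, `+`) - m2 == 0 |
                          abs(outer(d1, steps, `+`) - m2) < 1e-6))
      }
    }
    tested <- tested + 1L
  }
  expect_gte(tested, 5L)
})
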