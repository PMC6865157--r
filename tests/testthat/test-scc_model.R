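hwe <- function(q) c(q^2, 2 * q * (1 - q), (1 - q)^2)

test_that("case_genotype_freqs applies the proportional mixing", {
  f <- c(0.09, 0.42, 0.49)
  expect_equal(unname(case_genotype_freqs(f, 0, "dominant")), f)
  expect_equal(unname(case_genotype_freqs(f, 0, "recessive")), f)
  # two-line mixing formula evaluated by hand:
  # dominant: S = 0.51; DD: 0.8*0.09 + 0.2*0.09/0.51, Dd analogous, dd: 0.8*0.49
  expect_equal(unname(case_genotype_freqs(f, 0.2, "dominant")),
               c(0.1072941, 0.5007059, 0.392), tolerance = 1e-6)
  # recessive: DD gains the whole mass y
  expect_equal(unname(case_genotype_freqs(f, 0.2, "recessive")),
               c(0.272, 0.336, 0.392), tolerance = 1e-12)
})

test_that("case genotype frequencies stay on the simplex", {
  set.seed(8)
  for (i in 1:50) {
    f <- as.vector(stats::rmultinom(1, 60, c(0.2, 0.5, 0.3))) / 60
    y <- runif(1)
    for (mode in c("dominant", "recessive")) {
      if (mode == "dominant" && f[1] + f[2] == 0) next
      if (mode == "recessive" && f[1] + f[2] / 2 == 0) next
      out <- case_genotype_freqs(f, y, mode)
      expect_equal(sum(out), 1, tolerance = 1e-12)
      expect_true(all(out >= -1e-15))
    }
  }
  expect_error(case_genotype_freqs(c(0, 0, 1), 0.5, "dominant"),
               "unsatisfiable")
})

test_that("odds ratio at allele frequency 0.3 and proportion 0.2 is 1.3", {
  expect_equal(signif(or_from_y(hwe(0.3), 0.2, "dominant"), 2), 1.3)
})

test_that("or_from_y boundary and recessive values", {
  expect_equal(or_from_y(hwe(0.3), 0, "dominant"), 1, tolerance = 1e-12)
  expect_equal(or_from_y(hwe(0.3), 0, "recessive"), 1, tolerance = 1e-12)
  # oracle: case_genotype_freqs then allelic odds, evaluated by hand
  expect_equal(or_from_y(hwe(0.3), 0.2, "recessive"), 1.8333,
               tolerance = 1e-4)
})

test_that("or_from_y is strictly increasing in y", {
  for (mode in c("dominant", "recessive")) {
    ors <- sapply(seq(0, 1, by = 0.1), function(y)
      or_from_y(hwe(0.25), y, mode))
    expect_true(all(diff(ors) > 0))
  }
})

test_that("y_from_or inverts or_from_y to 1e-10", {
  for (mode in c("dominant", "recessive")) {
    for (f in list(hwe(0.3), hwe(0.05), c(0.2, 0.3, 0.5))) {
      for (y in c(0.01, 0.2, 0.9)) {
        or <- or_from_y(f, y, mode)
        expect_equal(y_from_or(f, or, mode), y, tolerance = 1e-10)
      }
    }
  }
  # inverted worked example
  expect_equal(y_from_or(hwe(0.3), 1.3, "dominant"), 0.2, tolerance = 0.01)
})

test_that("dominant feasibility bound is 2(1 - P_DD)/P_Dd - 1", {
  expect_equal(max_dominant_or(hwe(0.3)), 10 / 3, tolerance = 1e-10)
  expect_equal(max_dominant_or(c(0, 1, 0)), 1, tolerance = 1e-12)
  expect_error(y_from_or(hwe(0.3), 4, "dominant"), "bound")
  expect_error(max_dominant_or(c(0.5, 0, 0.5)), "P_Dd")
  # the bound is the forward map at y = 1
  set.seed(4)
  for (i in 1:100) {
    f <- as.vector(stats::rmultinom(1, 40, c(0.3, 0.4, 0.3))) / 40
    if (f[2] == 0 || f[1] + f[2] / 2 >= 1) next
    expect_equal(max_dominant_or(f), or_from_y(f, 1, "dominant"),
                 tolerance = 1e-10)
  }
})

test_that("penetrance reduces to the background risk at y = 0", {
  expect_equal(penetrance(hwe(0.3), 0, 0.01, "dominant"), 0.01,
               tolerance = 1e-12)
})

test_that("penetrance declines as the disease allele becomes common", {
  # grids keep the focal risk y*pli below the disease-genotype mass
  # (for a rare recessive variant the homozygote class is too small to
  # carry the causal mass at all -- that is an error, tested below)
  pen <- sapply(c(0.01, 0.1, 0.3), function(q)
    penetrance(hwe(q), 0.2, 0.01, "dominant"))
  expect_true(all(diff(pen) < 0))
  pen <- sapply(c(0.1, 0.3, 0.5), function(q)
    penetrance(hwe(q), 0.2, 0.01, "recessive"))
  expect_true(all(diff(pen) < 0))
  expect_error(penetrance(hwe(0.01), 0.2, 0.01, "recessive"),
               "unsatisfiable")
})

test_that("penetrance matches a two-cause enumeration oracle", {
  # oracle: enumerate the four (focal fulfilled) x (other causes fulfilled)
  # outcomes for a carrier of a disease genotype; disease occurs unless both
  # fail.  focal risk concentrates y*pli on the disease-genotype mass.
  q <- 0.1; y <- 0.5; pli <- 0.01
  f <- hwe(q)
  s <- f[1] + f[2]
  p_focal <- y * pli / s
  p_other <- (1 - y) * pli
  oracle <- 0
  for (focal in c(TRUE, FALSE)) {
    for (other in c(TRUE, FALSE)) {
      pr <- (if (focal) p_focal else 1 - p_focal) *
        (if (other) p_other else 1 - p_other)
      if (focal || other) oracle <- oracle + pr
    }
  }
  expect_equal(penetrance(f, y, pli, "dominant"), oracle, tolerance = 1e-12)
})

test_that("dominant OR declines toward 1 with allele frequency; recessive exceeds dominant", {
  y <- 0.2
  qs <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  dom <- sapply(qs, function(q) or_from_y(hwe(q), y, "dominant"))
  expect_true(all(diff(dom) < 0))
  expect_gt(dom[1], tail(dom, 1))
  for (q in c(0.05, 0.2, 0.5)) {
    expect_gte(or_from_y(hwe(q), y, "recessive"),
               or_from_y(hwe(q), y, "dominant"))
  }
})

test_that("disease_model validates its arguments", {
  expect_error(disease_model(integer(0), or = 2), "at least one")
  expect_error(disease_model(1, or = 2, y = 0.5), "exactly one")
  expect_error(disease_model(1), "exactly one")
  expect_error(disease_model(1, y = 1.5), "0, 1")
  m <- disease_model(c(2, 5), mode = "recessive", or = 3)
  expect_s3_class(m, "disease_model")
  expect_equal(m$pli, 0.01)
})

test_that("or_curve tabulates the forward map over a grid", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- or_curve(freqs = c(0.1, 0.3), y_values = c(0.2), path = path)
  expect_true(file.exists(path))
  row <- tab[tab$mode == "dominant" & tab$freq == 0.3, ]
  expect_equal(signif(row$or, 2), 1.3)
})
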