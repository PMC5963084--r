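test_that("reference statistics follow the median / median-absolute-difference definition", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(7, 7, 7, 7, 7),
             g3 = c(2, NA, 4, NA, 6))
  colnames(m) <- paste0("n", 1:5)
  ref <- build_reference(m)
  expect_equal(ref$m[ref$gene == "g1"], 3)
  expect_equal(ref$s[ref$gene == "g1"], 1)  # deviations {2,1,0,1,2}
  # constant gene: zero scale, uncallable
  expect_equal(ref$s[ref$gene == "g2"], 0)
  expect_false(ref$callable[ref$gene == "g2"])
  # missing values ignored; 3 non-missing normals is still callable
  expect_equal(ref$m[ref$gene == "g3"], 4)
  expect_true(ref$callable[ref$gene == "g3"])
  expect_equal(attr(ref, "n_normals"), 5L)
  expect_error(build_reference(m[, 0, drop = FALSE]), "no normal samples")
})

test_that("the normal-sample count is carried through unchanged", {
  m <- matrix(rnorm(2 * 295, 10), 2, 295,
              dimnames = list(c("a", "b"), paste0("n", 1:295)))
  expect_equal(attr(build_reference(m), "n_normals"), 295L)
})

test_that("Z-scores are exact at the reference location and scale", {
  normals <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(5, 5, 5, 5, 5))
  colnames(normals) <- paste0("n", 1:5)
  ref <- build_reference(normals)
  tumors <- cbind(t1 = c(g1 = 3, g2 = 7), t2 = c(g1 = 5, g2 = 5))
  z <- zscore(tumors, ref)
  expect_equal(z["g1", "t1"], 0)        # x = m
  expect_equal(z["g1", "t2"], 2)        # x = m + 2 s, exactly
  expect_true(all(is.na(z["g2", ])))    # zero scale: missing, never +/-Inf
})

test_that("genes absent from the reference drop with a warning; disjoint sets error", {
  normals <- rbind(g1 = 1:5)
  colnames(normals) <- paste0("n", 1:5)
  ref <- build_reference(normals)
  tumors <- rbind(g1 = c(3, 4), gX = c(1, 2))
  colnames(tumors) <- c("t1", "t2")
  expect_warning(z <- zscore(tumors, ref), "gX")
  expect_equal(rownames(z), "g1")
  expect_error(suppressWarnings(
    zscore(rbind(gY = c(1, 2)), ref)), "no genes shared")
})

test_that("expression calls use inclusive thresholds", {
  expect_equal(call_level(4.77), "high")     # reported exporter elevation
  expect_equal(call_level(-3.56), "low")     # reported target loss
  expect_equal(call_level(1.999), "normal")
  expect_equal(call_level(2), "high")        # boundary inclusive
  expect_equal(call_level(-2), "low")
  expect_equal(call_level(NA_real_), "normal")
  expect_error(call_level(1, thr_high = -1), "thr_high")
  calls <- expression_calls(matrix(c(2.5, NA), 2, 1,
                                   dimnames = list(c("a", "b"), "s1")))
  expect_equal(calls$level, c("high", "normal"))
  expect_equal(calls$callable, c(TRUE, FALSE))
})

test_that("zscore matches the brute-force definition to 1e-12", {
  set.seed(42)
  for (rep in 1:20) {
    ng <- sample(2:10, 1); ns <- sample(3:10, 1)
    normals <- matrix(rlnorm(ng * 8, 3, 1), ng, 8,
                      dimnames = list(paste0("g", 1:ng), paste0("n", 1:8)))
    tumors <- matrix(rlnorm(ng * ns, 3, 1), ng, ns,
                     dimnames = list(paste0("g", 1:ng), paste0("t", 1:ns)))
    z <- zscore(tumors, build_reference(normals))
    expect_equal(z, oracle_zscore(tumors, normals), tolerance = 1e-12)
  }
})

test_that("Z-scores are invariant to shared affine transforms", {
  set.seed(7)
  normals <- matrix(rlnorm(5 * 10, 4, 0.5), 5, 10,
                    dimnames = list(paste0("g", 1:5), paste0("n", 1:10)))
  tumors <- matrix(rlnorm(5 * 6, 4, 0.5), 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("t", 1:6)))
  z0 <- zscore(tumors, build_reference(normals))
  for (i in 1:25) {
    cshift <- rnorm(1, 0, 50)
    kscale <- rlnorm(1, 0, 1)
    z1 <- zscore(kscale * (tumors + cshift),
                 build_reference(kscale * (normals + cshift)))
    expect_equal(z1, z0, tolerance = 1e-9)
  }
})

test_that("the flagged fraction shrinks as the threshold grows", {
  set.seed(11)
  normals <- matrix(rlnorm(20 * 50, 3, 1), 20, 50,
                    dimnames = list(paste0("g", 1:20), paste0("n", 1:50)))
  tumors <- matrix(rlnorm(20 * 200, 3, 1), 20, 200,
                   dimnames = list(paste0("g", 1:20), paste0("t", 1:200)))
  z <- zscore(tumors, build_reference(normals))
  frac <- vapply(c(1, 1.5, 2, 2.5, 3, 4),
                 function(t) mean(abs(z) >= t, na.rm = TRUE), numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_lt(frac[3], 0.25)
})

test_that("expression matrices round-trip through TSV", {
  m <- matrix(c(1.5, 2, NA, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  expect_equal(read_expression_matrix(path), m)
})
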