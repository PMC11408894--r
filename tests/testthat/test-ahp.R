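test_that("scale table maps proportion differences onto the 1-9 scale", {
  st <- build_scale_table(c(0.5, 0.3, 0.2))
  expect_equal(st$d_max, 0.3)
  expect_equal(scale_value(st, 0.3), 9L)   # maximum difference
  expect_equal(scale_value(st, 0), 1L)     # equal importance
  expect_equal(scale_value(st, 0.1), 1L + as.integer(floor(8 * 0.1 / 0.3)))

  uniform <- build_scale_table(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(scale_value(uniform, 0), 1L)
  expect_true(all(build_judgment_matrix(rep(0.25, 4)) == 1))

  two <- build_judgment_matrix(c(0.7, 0.3))
  expect_equal(two[1, 2], 9)
  expect_equal(two[2, 1], 1 / 9)
})

test_that("judgment matrices are reciprocal with scale-mapped entries", {
  m <- build_judgment_matrix(c(0.5, 0.3, 0.2))
  expect_equal(diag(m), rep(1, 3))
  expect_equal(m[1, 3], 9)
  expect_equal(m[3, 1], 1 / 9)
  expect_true(all(abs(m * t(m) - 1) < 1e-12))

  flipped <- build_judgment_matrix(c(0.2, 0.6))
  expect_equal(flipped[1, 2], 1 / 9)
  expect_equal(flipped[2, 1], 9)

  expect_error(build_judgment_matrix(c(0.5, 1.2)), class = "useis_validation_error")
  expect_error(build_judgment_matrix(0.4), class = "useis_validation_error")
})

test_that("power iteration finds the principal eigenpair", {
  flat <- principal_eigenvector(matrix(1, 4, 4))
  expect_equal(flat$lambda_max, 4, tolerance = 1e-10)
  expect_equal(unname(flat$weights), rep(0.25, 4), tolerance = 1e-10)

  w <- c(0.6, 0.3, 0.1)
  consistent <- outer(w, w, `/`)
  fit <- principal_eigenvector(consistent)
  expect_equal(fit$lambda_max, 3, tolerance = 1e-10)
  expect_equal(unname(fit$weights), w, tolerance = 1e-10)

  m <- matrix(c(1, 3, 5, 1 / 3, 1, 3, 1 / 5, 1 / 3, 1), 3, byrow = TRUE)
  dense <- eigen(m)
  lambda_oracle <- max(Re(dense$values))
  v <- Re(dense$vectors[, which.max(Re(dense$values))])
  w_oracle <- v / sum(v)
  fit <- principal_eigenvector(m)
  expect_equal(fit$lambda_max, lambda_oracle, tolerance = 1e-8)
  expect_equal(unname(fit$weights), w_oracle, tolerance = 1e-8)
})

test_that("consistency ratio matches the dense-eigensolver oracle", {
  w <- c(0.5, 0.25, 0.25)
  rep0 <- consistency_check(outer(w, w, `/`))
  expect_equal(rep0$CI, 0, tolerance = 1e-12)
  expect_equal(rep0$CR, 0, tolerance = 1e-12)
  expect_true(rep0$pass)

  m <- matrix(c(1, 3, 5, 1 / 3, 1, 3, 1 / 5, 1 / 3, 1), 3, byrow = TRUE)
  lambda_oracle <- max(Re(eigen(m)$values))
  cr_oracle <- ((lambda_oracle - 3) / 2) / 0.58
  rep1 <- consistency_check(m)
  expect_equal(rep1$CR, cr_oracle, tolerance = 1e-8)

  # strongly cyclic preferences: far beyond the 0.1 threshold
  bad <- matrix(c(1, 9, 1 / 9, 1 / 9, 1, 9, 9, 1 / 9, 1), 3, byrow = TRUE)
  rep2 <- consistency_check(bad)
  expect_gt(rep2$CR, 0.1)
  expect_false(rep2$pass)

  # order 2 is consistent by convention
  rep3 <- consistency_check(build_judgment_matrix(c(0.6, 0.4)))
  expect_equal(rep3$CR, 0)
  expect_true(rep3$pass)

  m11 <- withr::with_seed(1, random_reciprocal(11))
  expect_error(consistency_check(m11), class = "useis_validation_error")
  expect_silent(consistency_check(m11, ri_table = rep(1.5, 11)))
})

test_that("weight synthesis multiplies through the hierarchy", {
  h <- hierarchy_frame("Sat", data.frame(
    indicator = c("A1", "A2", "B1", "B2"),
    criterion = c("A", "A", "B", "B")
  ))
  ok <- structure(list(n = 2L, lambda_max = 2, CI = 0, RI = 0, CR = 0, pass = TRUE),
                  class = "useis_consistency")
  out <- synthesize_weights(
    h, c(A = 0.6, B = 0.4),
    list(A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 0.5, B2 = 0.5)),
    reports = list(criteria = ok, A = ok, B = ok)
  )
  expect_equal(out$weights$indicators$global_weight, c(0.3, 0.3, 0.2, 0.2))
  expect_equal(sum(out$weights$indicators$global_weight), 1)
  expect_equal(out$combined$CR, 0)
  expect_true(out$combined$pass)

  single <- hierarchy_frame("Sat", data.frame(
    indicator = c("A1", "A2"), criterion = c("A", "A")
  ))
  out2 <- synthesize_weights(single, c(A = 1), list(A = c(A1 = 0.7, A2 = 0.3)),
                             reports = list(criteria = ok, A = ok))
  expect_equal(out2$weights$indicators$global_weight, c(0.7, 0.3))

  failing <- ok; failing$pass <- FALSE; failing$CR <- 0.12
  expect_error(
    synthesize_weights(h, c(A = 0.6, B = 0.4),
                       list(A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 0.5, B2 = 0.5)),
                       reports = list(criteria = ok, A = failing, B = ok)),
    regexp = "A", class = "useis_consistency_error"
  )
})

test_that("lambda_max is at least n, with equality only when consistent", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(3:7, 1)
      m <- random_reciprocal(n)
      fit <- principal_eigenvector(m)
      expect_gte(fit$lambda_max, n - 1e-9)
    }
  })
  # equality by construction for consistent matrices
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(3:7, 1)
      w <- runif(n, 0.05, 1)
      fit <- principal_eigenvector(outer(w, w, `/`))
      expect_equal(fit$lambda_max, n, tolerance = 1e-9)
      expect_equal(unname(fit$weights), w / sum(w), tolerance = 1e-10)
    }
  })
})

test_that("pipeline weights are permutation-equivariant and rank-monotone", {
  h <- hierarchy_frame("Sat", data.frame(
    indicator = paste0("I", 1:4), criterion = rep("C", 4)
  ))
  p <- c(I1 = 0.4, I2 = 0.3, I3 = 0.2, I4 = 0.1)
  base <- ahp_weights(h, p)$weights$indicators

  perm <- c("I3", "I1", "I4", "I2")
  h2 <- hierarchy_frame("Sat", data.frame(indicator = perm, criterion = rep("C", 4)))
  permuted <- ahp_weights(h2, p[perm])$weights$indicators
  expect_equal(
    setNames(permuted$global_weight, permuted$indicator)[base$indicator],
    setNames(base$global_weight, base$indicator)
  )

  # the proportion-to-scale mapping is monotone, so weights follow rank order
  withr::with_seed(11, {
    for (i in 1:20) {
      props <- sort(runif(5), decreasing = TRUE)
      props <- props / sum(props)
      names(props) <- paste0("I", 1:5)
      h5 <- hierarchy_frame("Sat", data.frame(
        indicator = names(props), criterion = rep("C", 5)
      ))
      w <- ahp_weights(h5, props)$weights$indicators$global_weight
      expect_true(all(diff(w) <= 1e-12))
    }
  })
})

test_that("single-indicator criteria get local weight one and pass trivially", {
  h <- hierarchy_frame("Sat", data.frame(
    indicator = c("A1", "B1", "B2"), criterion = c("A", "B", "B")
  ))
  fit <- ahp_weights(h, c(A1 = 0.5, B1 = 0.3, B2 = 0.2))
  expect_equal(fit$weights$indicators$local_weight[1], 1)
  expect_true(all(fit$consistency$pass))
  a_row <- fit$consistency[fit$consistency$set == "A", ]
  expect_equal(a_row$CR, 0)
})

test_that("judgment matrices and scale tables round-trip through CSV", {
  m <- build_judgment_matrix(c(0.5, 0.3, 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_judgment_matrix(m, path)
  expect_equal(read_judgment_matrix(path), m, ignore_attr = TRUE)

  st_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(upper = c(0.1, 0.2, 0.4), scale = c(1, 4, 9)),
            st_path, row.names = FALSE)
  st <- read_scale_table(st_path)
  expect_equal(scale_value(st, c(0.05, 0.15, 0.3)), c(1L, 4L, 9L))
  m2 <- build_judgment_matrix(c(0.35, 0.2), scale = st)
  expect_equal(m2[1, 2], 4)
})
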