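# quaternion algebra against the rotation-matrix oracle

test_that("axis-angle construction matches the closed-form cases", {
  expect_quat_equal(quat_from_axis_angle(c(0, 0, 1), 0), c(1, 0, 0, 0), 1e-15)
  expect_quat_equal(quat_from_axis_angle(c(0, 0, 1), 180), c(0, 0, 0, 1), 1e-15)
  expect_quat_equal(quat_from_axis_angle(c(1, 0, 0), 90),
                    c(sqrt(2) / 2, sqrt(2) / 2, 0, 0), 1e-15)
  expect_error(quat_from_axis_angle(c(1, 1, 0), 30), "unit")
  expect_error(quat(0, 0, 0, 0), "zero quaternion")
  expect_equal(axis_angle(c(2, 0, 0), 10, normalize = TRUE)$axis, c(1, 0, 0))
})

test_that("constructor renormalizes and canonicalizes", {
  q <- quat(2, 0, 0, 0)
  expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-12)
  expect_quat_equal(quat(-0.5, 0.5, 0.5, 0.5), c(0.5, -0.5, -0.5, -0.5), 1e-15)
  # w == 0: first non-zero imaginary component made positive
  expect_equal(unname(unclass(quat(0, -1, 0, 0))), c(0, 1, 0, 0))
})

test_that("Hamilton product composes rotations (matrix oracle)", {
  expect_quat_equal(quat_multiply(quat_identity(), quat(0.5, 0.5, 0.5, 0.5)),
                    c(0.5, 0.5, 0.5, 0.5), 1e-15)
  expect_quat_equal(quat_multiply(quat(0, 1, 0, 0), quat(0, 0, 1, 0)),
                    c(0, 0, 0, 1), 1e-15)  # i * j = k
  qz <- quat_from_axis_angle(c(0, 0, 1), 90)
  qx <- quat_from_axis_angle(c(1, 0, 0), 90)
  expect_lt(max(abs(quat_to_matrix(quat_multiply(qz, qx)) -
                    o_rot(c(0, 0, 1), 90) %*% o_rot(c(1, 0, 0), 90))), 1e-12)
  set.seed(11)
  for (i in 1:200) {
    a <- o_random_rot(); b <- o_random_rot()
    qa <- quat_from_axis_angle(a$axis, a$theta)
    qb <- quat_from_axis_angle(b$axis, b$theta)
    expect_lt(o_mat_angle(quat_to_matrix(quat_multiply(qa, qb)), a$m %*% b$m), 1e-9)
  }
})

test_that("inverse is the conjugate / matrix transpose, and an involution", {
  expect_quat_equal(quat_inverse(quat_identity()), c(1, 0, 0, 0), 1e-15)
  set.seed(12)
  for (i in 1:100) {
    r <- o_random_rot()
    q <- quat_from_axis_angle(r$axis, r$theta)
    expect_quat_equal(quat_multiply(q, quat_inverse(q)), c(1, 0, 0, 0), 1e-12)
    expect_lt(max(abs(quat_to_matrix(quat_inverse(q)) - t(r$m))), 1e-12)
    expect_quat_equal(quat_inverse(quat_inverse(q)), q, 1e-15)
  }
})

test_that("vector rotation matches the matrix oracle and preserves geometry", {
  expect_equal(quat_rotate(quat_identity(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(quat_rotate(quat_from_axis_angle(c(0, 0, 1), 90), c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:200) {
    r <- o_random_rot()
    q <- quat_from_axis_angle(r$axis, r$theta)
    v <- stats::rnorm(3)
    u <- stats::rnorm(3)
    expect_equal(quat_rotate(q, v), as.numeric(r$m %*% v), tolerance = 1e-12)
    expect_equal(sqrt(sum(quat_rotate(q, v)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
    expect_equal(sum(quat_rotate(q, v) * quat_rotate(q, u)), sum(v * u),
                 tolerance = 1e-10)
  }
})

test_that("Euler conversion: single-axis cases and full round trips", {
  expect_equal(as.numeric(quat_to_euler(quat_identity())), c(0, 0, 0))
  expect_equal(as.numeric(quat_to_euler(quat_from_axis_angle(c(1, 0, 0), 30))),
               c(30, 0, 0), tolerance = 1e-12)
  set.seed(14)
  # principal domain: |x| <= 85 keeps clear of the lock
  for (i in 1:250) {
    e <- c(stats::runif(1, -85, 85), stats::runif(2, -179, 179))
    back <- as.numeric(quat_to_euler(quat_from_euler(e)))
    expect_equal(back, e, tolerance = 1e-9)
    # quaternion and oracle matrix agree on the decomposition
    expect_equal(as.numeric(quat_to_euler(quat_from_euler(e))), o_mat_euler(o_euler_mat(e)),
                 tolerance = 1e-9)
  }
})

test_that("gimbal lock tie-break: z zeroed, recomposition exact", {
  for (px in c(90, -90)) {
    for (resid in c(0, 25, -140)) {
      q <- quat_multiply(quat_multiply(quat_from_axis_angle(c(0, 0, 1), resid),
                                       quat_from_axis_angle(c(1, 0, 0), px)),
                         quat_from_axis_angle(c(0, 1, 0), 10))
      e <- quat_to_euler(q)
      expect_equal(unname(e[3]), 0)
      expect_equal(unname(e[1]), px, tolerance = 1e-6)
      # the locked degree of freedom lands on y; recomposition is exact
      expect_lt(o_mat_angle(quat_to_matrix(quat_from_euler(e)), quat_to_matrix(q)), 1e-6)
    }
  }
})

test_that("relative rotation cancels the common frame", {
  q <- quat_from_axis_angle(c(0, 1, 0), 40)
  expect_quat_equal(quat_relative(q, q), c(1, 0, 0, 0), 1e-12)
  expect_quat_equal(quat_relative(quat_identity(), q), q, 1e-15)
  set.seed(15)
  for (i in 1:100) {
    p <- o_random_rot(); c_ <- o_random_rot(); g <- o_random_rot()
    qp <- quat_from_axis_angle(p$axis, p$theta)
    qc <- quat_from_axis_angle(c_$axis, c_$theta)
    qg <- quat_from_axis_angle(g$axis, g$theta)
    r1 <- quat_relative(qp, qc)
    r2 <- quat_relative(quat_multiply(qg, qp), quat_multiply(qg, qc))
    expect_quat_equal(r1, r2, 1e-9)
  }
})

test_that("multiplication is associative", {
  set.seed(16)
  for (i in 1:50) {
    qs <- lapply(1:3, function(j) { r <- o_random_rot(); quat_from_axis_angle(r$axis, r$theta) })
    lhs <- quat_multiply(quat_multiply(qs[[1]], qs[[2]]), qs[[3]])
    rhs <- quat_multiply(qs[[1]], quat_multiply(qs[[2]], qs[[3]]))
    expect_quat_equal(lhs, rhs, 1e-12)
  }
})
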