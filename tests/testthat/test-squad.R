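toggle_edges <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                           sign = c(-1, -1), class = "TF")

test_that("the activation sigmoid is anchored and monotone for any gain", {
  for (h in c(1, 5, 10, 50)) {
    expect_equal(squad_activation(0, h), 0, tolerance = 1e-12)
    expect_equal(squad_activation(0.5, h), 0.5, tolerance = 1e-12)
    expect_equal(squad_activation(1, h), 1, tolerance = 1e-12)
  }
  expect_lt(squad_activation(0.3, 10), squad_activation(0.7, 10))
  om <- seq(0, 1, 0.05)
  expect_true(all(diff(squad_activation(om, 10)) > 0))
  # sharp-switch limit: the gap to 1 closes like exp(-h (omega - 0.5))
  expect_gt(squad_activation(0.6, 50), 1 - 1e-2)
  expect_gt(squad_activation(0.6, 100), 1 - 1e-3)
  expect_error(squad_activation(1.2, 10), "\\[0,1\\]")
  expect_error(squad_activation(0.5, -1), "h must be")
})

test_that("the regulatory input combines activators and inhibitors as specified", {
  sys <- squad_system(data.frame(
    regulator = c("a1", "a2", "b1"), target = c("t", "t", "t"),
    sign = c(1, 1, -1), class = "TF"))
  x <- c(a1 = 0.5, a2 = 0.5, b1 = 0, t = 0)
  expect_equal(squad_omega(sys, "t", x), (3 / 2) * (1 / 2), tolerance = 1e-12)
  x2 <- c(a1 = 1, a2 = 0, b1 = 0, t = 0)
  expect_equal(squad_omega(sys, "t", x2), (3 / 2) * (1 / 2),
               tolerance = 1e-12)
  # a single saturated activator drives the input to 1
  sys1 <- squad_system(data.frame(regulator = "a1", target = "t",
                                  sign = 1, class = "TF"))
  expect_equal(squad_omega(sys1, "t", c(a1 = 1, t = 0)), (2 / 1) * (1 / 2) * 1,
               tolerance = 1e-12)
  x3 <- c(a1 = 0, a2 = 0, b1 = 1, t = 0)
  expect_equal(squad_omega(sys, "t", x3), 0, tolerance = 1e-12)
  expect_true(is.na(squad_omega(sys, "a1", x)))  # unregulated input node
  expect_error(squad_omega(sys, "t", c(a1 = 2, a2 = 0, b1 = 0, t = 0)),
               "\\[0,1\\]")
})

test_that("conflicting duplicate regulation is rejected at construction", {
  bad <- data.frame(regulator = c("a", "a"), target = c("t", "t"),
                    sign = c(1, -1), class = "TF")
  expect_error(squad_system(bad), "both activates and inhibits")
  expect_error(squad_system(toggle_edges, h = -1), "h must be")
  expect_error(squad_system(toggle_edges, gamma = 0), "gamma")
  expect_error(squad_system(toggle_edges, clamp = c(A = 1.5)), "\\[0,1\\]")
})

test_that("an unregulated node decays to zero and clamps hold exactly", {
  sys <- squad_system(data.frame(regulator = "in1", target = "g",
                                 sign = 1, class = "TF"))
  tr <- squad_integrate(sys, x0 = c(in1 = 0.8, g = 0))
  expect_true(tr$steady)
  expect_lt(tr$final[["in1"]], 1e-4)
  sysc <- squad_system(data.frame(regulator = "in1", target = "g",
                                  sign = 1, class = "TF"),
                       clamp = c(in1 = 1))
  trc <- squad_integrate(sysc, x0 = c(in1 = 1, g = 0))
  expect_true(all(trc$x[, "in1"] == 1))
  expect_gt(trc$final[["g"]], 0.9)   # fully activated target approaches 1
  expect_error(squad_integrate(sys, dt = 0), "dt and t_end")
})

test_that("the toggle switch is bistable and agrees with an independent ODE oracle", {
  sys <- squad_system(toggle_edges)
  orc <- function(x0) {
    f <- function(t, x, p) {
      omA <- 1 - (2 / 1) * x[["B"]] / (1 + x[["B"]])
      omB <- 1 - (2 / 1) * x[["A"]] / (1 + x[["A"]])
      act <- function(om) {
        e1 <- exp(0.5 * 10); e2 <- exp(-10 * (om - 0.5))
        (-e1 + e2) / ((1 - e1) * (1 + e2))
      }
      list(c(act(omA) - x[["A"]], act(omB) - x[["B"]]))
    }
    out <- deSolve::lsoda(x0, seq(0, 60, 1), f, NULL,
                          rtol = 1e-10, atol = 1e-10)
    out[nrow(out), c("A", "B")]
  }
  t1 <- squad_integrate(sys, x0 = c(A = 1, B = 0))
  expect_true(t1$steady)
  expect_equal(unname(t1$final[c("A", "B")]), unname(orc(c(A = 1, B = 0))),
               tolerance = 1e-4)
  expect_gt(t1$final[["A"]], 0.9); expect_lt(t1$final[["B"]], 0.1)
  t2 <- squad_integrate(sys, x0 = c(A = 0, B = 1))
  expect_equal(unname(t2$final[c("A", "B")]), unname(orc(c(A = 0, B = 1))),
               tolerance = 1e-4)
  expect_gt(t2$final[["B"]], 0.9); expect_lt(t2$final[["A"]], 0.1)
})

test_that("trajectories are forward-invariant in the unit hypercube", {
  set.seed(17)
  nodes <- paste0("n", 1:8)
  edges <- data.frame(regulator = sample(nodes, 14, replace = TRUE),
                      target = sample(nodes, 14, replace = TRUE),
                      sign = sample(c(1, -1), 14, replace = TRUE),
                      class = "TF")
  edges <- edges[edges$regulator != edges$target, ]
  edges <- edges[!duplicated(edges[, c("regulator", "target")]), ]
  sys <- squad_system(edges)
  x0 <- setNames(runif(length(sys$nodes)), sys$nodes)
  tr <- squad_integrate(sys, x0 = x0, t_end = 30)
  expect_true(all(tr$x >= 0 & tr$x <= 1))
})

test_that("halving the step size leaves steady states essentially unchanged", {
  sys <- squad_system(toggle_edges)
  a <- squad_integrate(sys, x0 = c(A = 1, B = 0), dt = 0.05)
  b <- squad_integrate(sys, x0 = c(A = 1, B = 0), dt = 0.025)
  expect_lt(max(abs(a$final - b$final)), 1e-6)
})

test_that("Boolean fixed points match exhaustive enumeration and seed the ODE", {
  sys <- squad_system(toggle_edges)
  fx <- boolean_attractors(sys)
  expect_equal(nrow(fx), 2)
  keys <- apply(fx[, c("A", "B")], 1, paste, collapse = "")
  expect_setequal(keys, c("10", "01"))
  # each Boolean fixed point relaxes to a continuous state that rounds back
  for (i in 1:2) {
    x0 <- setNames(as.numeric(fx[i, ]), colnames(fx))
    tr <- squad_integrate(sys, x0 = x0)
    expect_equal(unname(round(tr$final)), unname(fx[i, ]))
  }
  # self-activator: both off and on are fixed
  sa <- squad_system(data.frame(regulator = "s", target = "s",
                                sign = 1, class = "TF"))
  fs <- boolean_attractors(sa)
  expect_setequal(as.vector(fs), c(0L, 1L))
  # cascade: the input holds, the target copies it
  ca <- squad_system(data.frame(regulator = "in1", target = "g",
                                sign = 1, class = "TF"))
  fc <- boolean_attractors(ca)
  expect_equal(nrow(fc), 2)
  expect_true(all(fc[, "in1"] == fc[, "g"]))
})

test_that("perturbation scans report activation changes of direct targets", {
  edges <- data.frame(regulator = "TF1", target = paste0("g", 1:10),
                      sign = 1, class = "TF")
  sys <- squad_system(edges)
  scan <- perturbation_scan(sys, "TF1", 0, 1)
  tg <- scan[scan$node != "TF1", ]
  expect_true(all(tg$delta > 0.2))
  null <- perturbation_scan(sys, "TF1", 0, 0)
  expect_true(all(null$delta == 0))
  expect_error(perturbation_scan(sys, "nope", 0, 1), "unknown node")
})
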