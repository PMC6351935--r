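test_that("zone weights follow the three-zone decay with inclusive bounds", {
  sc <- decay_scheme()
  expect_equal(zone_weight(5, sc), 1.00)
  expect_equal(zone_weight(15, sc), 0.42)
  expect_equal(zone_weight(25, sc), 0.09)
  expect_equal(zone_weight(35, sc), 0)
  # right-closed zone boundaries
  expect_equal(zone_weight(c(0, 10, 20, 30), sc), c(1.00, 1.00, 0.42, 0.09))
  expect_equal(zone_weight(Inf, sc), 0)
  expect_error(zone_weight(-1, sc), "non-negative")
})

test_that("decay schemes are validated", {
  expect_error(decay_scheme(c(10, 20), c(1, 0.5, 0.1)), "same length")
  expect_error(decay_scheme(c(20, 10, 30), c(1, 0.5, 0.1)), "increasing")
  expect_error(decay_scheme(c(10, 20, 30), c(0.5, 0.5, 0.1)), "decreasing")
})

# Worked example, verified by hand arithmetic:
#   S_j = 2; populations 500 @ 5 min, 600 @ 15 min, 400 @ 25 min
#   denominator = 500*1.00 + 600*0.42 + 400*0.09 = 788 ; R_j = 2/788
#   a = R_j * (1.00, 0.42, 0.09); mean = (2/788)*(1.51/3)
#   spar = 3/1.51 * (1.00, 0.42, 0.09)
worked_example <- function() {
  times <- matrix(c(5, 15, 25), nrow = 1,
                  dimnames = list("f1", c("p1", "p2", "p3")))
  pops <- c(500, 600, 400)
  e2sfca(times, providers = 2, population = pops)
}

test_that("step 1 reproduces the hand-computed provider ratio", {
  r <- step1_provider_ratio(
    2, c(p1 = 5, p2 = 15, p3 = 25),
    data.frame(id = c("p1", "p2", "p3"), population = c(500, 600, 400)))
  expect_equal(r$r_j, 2 / 788, tolerance = 1e-12)
  expect_false(r$catchment_empty)
  # single-term case
  r1 <- step1_provider_ratio(1, c(a = 5), data.frame(id = "a",
                                                     population = 1000))
  expect_equal(r1$r_j, 0.001)
  # empty catchment: nothing within the last break
  r0 <- step1_provider_ratio(3, c(a = 45), data.frame(id = "a",
                                                      population = 1000))
  expect_equal(r0$r_j, 0)
  expect_true(r0$catchment_empty)
  expect_error(step1_provider_ratio(
    1, c(a = 5), data.frame(id = "a", population = -10)), "negative")
})

test_that("step 2 sums decay-weighted ratios and is additive", {
  a <- step2_accessibility(c(f1 = 2 / 788), c(f1 = 5))
  expect_equal(a, 2 / 788, tolerance = 1e-12)
  expect_equal(step2_accessibility(c(f1 = 1), numeric(0)), 0)
  # duplicating a facility doubles the index
  a2 <- step2_accessibility(c(f1 = 2 / 788, f2 = 2 / 788),
                            c(f1 = 5, f2 = 5))
  expect_equal(a2, 2 * a)
})

test_that("the worked example flows through SPAR to the frozen values", {
  res <- worked_example()
  expect_equal(res$ratios$r_j, 2 / 788, tolerance = 1e-12)
  a <- res$access$a_index
  expect_equal(a, (2 / 788) * c(1.00, 0.42, 0.09), tolerance = 1e-12)
  sp <- spar(a)
  expect_equal(sp, (3 / 1.51) * c(1.00, 0.42, 0.09), tolerance = 1e-9)
  expect_equal(sp, c(1.9867549669, 0.8344370861, 0.1788079470),
               tolerance = 1e-9)
})

test_that("SPAR is a mean-one normalization, invariant to supply scaling", {
  expect_equal(spar(c(3, 3, 3)), c(1, 1, 1))
  a <- c(0.004, 0, 0.001, 0.0002)
  expect_equal(mean(spar(a)), 1, tolerance = 1e-12)
  # doubling every S_j doubles a and leaves SPAR unchanged
  expect_equal(spar(2 * a), spar(a))
  expect_error(spar(c(0, 0)), "undefined")
  expect_error(spar(c(-1, 2)), "non-negative")
})

test_that("supply is conserved: total weighted access equals served supply", {
  set.seed(42)
  for (rep in 1:5) {
    nf <- sample(3:6, 1); np <- sample(5:12, 1)
    tmat <- matrix(runif(nf * np, 0, 45), nf, np)  # some pairs out of range
    S <- sample(1:5, nf, replace = TRUE)
    P <- sample(400:700, np, replace = TRUE)
    res <- e2sfca(tmat, S, P)
    lhs <- sum(P * res$access$a_index)
    rhs <- sum(S[!res$ratios$catchment_empty])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("adding a facility or supply never decreases access", {
  set.seed(1)
  tmat <- matrix(runif(12, 0, 40), 3, 4)
  S <- c(2, 1, 3); P <- c(500, 650, 420, 580)
  base <- e2sfca(tmat, S, P)$access$a_index
  more <- e2sfca(rbind(tmat, runif(4, 0, 40)), c(S, 2), P)$access$a_index
  expect_true(all(more >= base - 1e-12))
  richer <- e2sfca(tmat, S + c(0, 5, 0), P)$access$a_index
  expect_true(all(richer >= base - 1e-12))
})

test_that("quantile classes isolate zeros and balance counts", {
  expect_equal(classify_quantiles(c(0, 0, 0)), rep("no access", 3))
  ten <- classify_quantiles(seq(0.1, 1, by = 0.1), n_classes = 5)
  expect_equal(as.vector(table(ten)), rep(2L, 5))
  mixed <- classify_quantiles(c(0, 0.5, 0, 2, 1))
  expect_equal(sum(mixed == "no access"), 2L)
  expect_equal(sum(classify_quantiles(c(0, 0.5, 0, 2, 1),
                                      n_classes = 3) == "no access"), 2L)
})

test_that("shortage summaries add up areas, people, and percentages", {
  rec <- data.frame(location_id = sprintf("d%d", 1:4),
                    spar = c(0, 1.2, 0, 0.4))
  pop <- data.frame(id = sprintf("d%d", 1:4),
                    population = c(500, 700, 600, 400),
                    area_km2 = c(1.2, 2.0, 0.8, 1.5))
  s <- shortage_summary(rec, pop)
  expect_equal(s$area_km2, 2.0)
  expect_equal(s$population, 1100)
  expect_equal(s$percent_of_total, 50.0)
  none <- shortage_summary(transform(rec, spar = c(1, 2, 3, 4)), pop)
  expect_equal(none$population, 0)
  expect_equal(none$percent_of_total, 0)
  expect_error(shortage_summary(rec, pop[-1, ]), "same location ids")
})
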