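## Cube geometry, mask inheritance, per-cube examination, and the three
## search drivers, including the pruning-soundness, parity and economy
## properties.

toy <- build_toy_network()
toy_tm <- compute_theoretical_maxima(toy, 1)

test_that("cube bounds follow the level geometry on all three axes", {
  b0 <- cube_bounds(toy_tm, 0, 1, 1, 1)
  expect_equal(b0$gr, c(0, 3)); expect_equal(b0$pr, c(0, 3))
  expect_equal(b0$sf, c(0, 26))  # SF axis spans twice the nominal scale
  b1 <- cube_bounds(toy_tm, 1, 1, 1, 1)
  expect_equal(b1$gr, c(0, 1.5)); expect_equal(b1$pr, c(0, 1.5))
  expect_equal(b1$sf, c(0, 13))
  expect_equal(cube_bounds(toy_tm, 1, 1, 1, 2)$sf[2], 26)
  expect_error(cube_bounds(toy_tm, 1, 3, 1, 1), "out of range")
})

test_that("cubes at one level tile the box exactly", {
  for (n in 0:2) {
    P <- 2^n
    gr_lo <- sort(unlist(lapply(1:P, function(i)
      cube_bounds(toy_tm, n, i, 1, 1)$gr[1])))
    gr_hi <- sort(unlist(lapply(1:P, function(i)
      cube_bounds(toy_tm, n, i, 1, 1)$gr[2])))
    expect_equal(gr_lo, (0:(P - 1)) * 3 / P)
    expect_equal(gr_hi, (1:P) * 3 / P)
    expect_equal(P^3, 8^n)  # cube-count identity
  }
})

test_that("children inherit the parent feasibility flag as their mask", {
  g <- feasibility_grid(2)
  g$c[] <- 0L
  g$c[1, 2, 1] <- 1L
  child <- refine_mask(g)
  expect_equal(child$P, 4L)
  on_idx <- which(child$d == 1L, arr.ind = TRUE)
  expect_equal(nrow(on_idx), 8)  # exactly the 8 children
  expect_true(all(ceiling(on_idx[, 1] / 2) == 1 &
                  ceiling(on_idx[, 2] / 2) == 2 &
                  ceiling(on_idx[, 3] / 2) == 1))
  # all-feasible parent -> full mask; root -> 8 cubes explored at P = 2
  g$c[] <- 1L
  expect_true(all(refine_mask(g)$d == 1L))
  root <- feasibility_grid(1)
  root$c[1, 1, 1] <- 1L
  expect_true(all(refine_mask(root)$d == 1L))
})

test_that("examining the whole space proposes and rejects the unused branch", {
  ex <- examine_cube(toy, cube_bounds(toy_tm, 0, 1, 1, 1), toy_params())
  expect_equal(ex$c_flag, 1L)
  expect_setequal(ex$strategy$K, c("R2", "R4", "R5"))
  expect_equal(ex$strategy$GR, 3, tolerance = 1e-7)
  expect_equal(ex$strategy$PR, 0, tolerance = 1e-7)
  expect_false(ex$strategy$accepted)
})

test_that("an empty sub-space is flagged infeasible and yields no strategy", {
  # high-SF slab with low production: total flux cannot reach 13
  ex <- examine_cube(toy, box_constraint(c(0, 1.5), c(0, 1.5), c(13, 26)),
                     toy_params())
  expect_equal(ex$c_flag, 0L)
  expect_null(ex$strategy)
  expect_equal(ex$lp_count, 1L)
  # box entirely above the growth maximum
  ex2 <- examine_cube(toy, box_constraint(c(4, 5), c(0, 3), c(0, 26)),
                      toy_params())
  expect_equal(ex2$c_flag, 0L)
})

test_that("the dynamic search returns the growth-coupling knockout of the demo network", {
  res <- run_dyncubeprod(toy, toy_params(n_max = 5))
  expect_false(is.null(res$strategy))
  expect_true(res$strategy$accepted)
  expect_equal(res$strategy$K, "R3")
  expect_equal(res$strategy$GR, 1, tolerance = 1e-7)
  expect_equal(res$strategy$PR, 2, tolerance = 1e-7)
  # re-validating the reported strategy from scratch reproduces it
  val <- validate_deletion(toy, res$strategy$K)
  expect_equal(val$gr_max, res$strategy$GR, tolerance = 1e-9)
  expect_equal(val$pr_min, res$strategy$PR, tolerance = 1e-9)
})

test_that("a root-only budget rejects the whole-space candidate and fails", {
  res <- run_dyncubeprod(toy, toy_params(n_max = 0))
  expect_null(res$strategy)
  expect_equal(unname(res$levels[["1"]]["examined"]), 1L)
  expect_equal(unname(res$levels[["1"]]["rejected"]), 1L)
})

test_that("the static cube scan at P = 2 examines 8 sub-spaces, 3 of them empty", {
  cp <- run_cubeprod(toy, toy_params(), P = 2)
  expect_equal(nrow(cp$trace), 8)
  expect_equal(sum(cp$trace$status == "infeasible"), 3)
  # the three empty sub-spaces are the high-SF slabs that cannot reach
  # SF = 13; the fourth high-SF slab contains the SF = 13 boundary vertex
  # (the growth-coupled solution itself) and is genuinely feasible
  empty <- cp$trace[cp$trace$status == "infeasible", c("i", "j", "k")]
  expect_true(all(empty$k == 2))
  feas_k2 <- cp$trace[cp$trace$k == 2 & cp$trace$status != "infeasible", ]
  expect_equal(nrow(feas_k2), 1)
  expect_equal(unname(unlist(feas_k2[, c("i", "j")])), c(1, 2))
})

test_that("static and dynamic searches agree on success at every level cap", {
  fixtures <- c(list(toy), lapply(c(5, 9, 13, 17), random_fixture))
  params_for <- function(model) {
    if (identical(model, toy)) toy_params() else
      search_params(min_growth = 0.1, min_target = 0.1)
  }
  for (model in fixtures) {
    p <- params_for(model)
    for (n in 0:3) {
      P <- 2^n
      p_cap <- search_params(min_growth = p$min_growth,
                             min_target = p$min_target, n_max = n)
      dyn_ok <- !is.null(run_dyncubeprod(model, p_cap)$strategy)
      cube_ok <- any(vapply(0:n, function(m) {
        length(run_cubeprod(model, p, P = 2^m,
                            stop_at_first = TRUE)$accepted) > 0
      }, logical(1)))
      expect_equal(dyn_ok, cube_ok,
                   info = sprintf("fixture %s at P=%d",
                                  model$reaction_ids[1], P))
    }
  }
})

test_that("every cube skipped by the dynamic search is independently infeasible", {
  fixtures <- c(list(toy), lapply(1:12, random_fixture))
  for (model in fixtures) {
    mg <- if (identical(model, toy)) 1 else 0.1
    p <- search_params(min_growth = mg, min_target = mg, n_max = 3)
    res <- run_dyncubeprod(model, p)
    skips <- res$trace[res$trace$status == "skipped", , drop = FALSE]
    tm <- res$maxima
    if (nrow(skips)) {
      for (r in seq_len(nrow(skips))) {
        n <- as.integer(round(log2(skips$P[r])))
        box <- cube_bounds(tm, n, skips$i[r], skips$j[r], skips$k[r])
        expect_equal(min_total_flux(model, box)$status, "infeasible",
                     info = sprintf("skipped cube P=%d (%d,%d,%d)",
                                    skips$P[r], skips$i[r], skips$j[r],
                                    skips$k[r]))
      }
    }
  }
})

test_that("pruning never solves more LPs than the static scans", {
  fixtures <- c(list(toy), lapply(c(5, 9), random_fixture))
  for (model in fixtures) {
    mg <- if (identical(model, toy)) 1 else 0.1
    p3 <- search_params(min_growth = mg, min_target = mg, n_max = 3)
    dyn <- run_dyncubeprod(model, p3)
    cube_total <- sum(vapply(0:3, function(n) {
      run_cubeprod(model, p3, P = 2^n)$lp_count
    }, numeric(1)))
    expect_lte(dyn$lp_count, cube_total)
    # examined cubes never exceed the full enumeration, strictly fewer
    # once any cube is infeasible at an earlier level
    lv <- do.call(rbind, dyn$levels)
    n_levels <- nrow(lv)
    full <- sum(8^(0:(n_levels - 1)))
    expect_lte(sum(lv[, "examined"]), full)
    if (any(lv[-n_levels, "infeasible"] > 0)) {
      expect_lt(sum(lv[, "examined"]), full)
    }
  }
})

test_that("the 2-D grid search cannot couple the demonstration network", {
  # the worked grid cell: minimum-flux solution splits over both branches
  gp_box <- box_constraint(c(0.75, 1.5), c(1.5, 2.25), c(0, Inf))
  fd <- min_total_flux(toy, gp_box)
  expect_equal(unname(fd$x), c(3, 1.5, 1.5, 1.5, 0, 1.5, 1.5),
               tolerance = 1e-8)
  ex <- examine_cube(toy, gp_box, toy_params())
  expect_setequal(ex$strategy$K, "R5")
  expect_false(ex$strategy$accepted)
  # the point cell at the optimum still validates to (3, 0): rejected
  ex2 <- examine_cube(toy, box_constraint(c(1, 1), c(2, 2), c(0, Inf)),
                      toy_params())
  expect_equal(ex2$strategy$GR, 3, tolerance = 1e-7)
  expect_equal(ex2$strategy$PR, 0, tolerance = 1e-7)
  # no accepted strategy at any tested grid resolution
  for (P in c(1, 2, 4, 8)) {
    gp <- run_gridprod(toy, toy_params(), P = P)
    expect_length(gp$accepted, 0)
  }
})

test_that("identical inputs give identical strategies and provenance", {
  r1 <- run_dyncubeprod(toy, toy_params())
  r2 <- run_dyncubeprod(toy, toy_params())
  expect_identical(r1$strategy$K, r2$strategy$K)
  expect_identical(r1$strategy$found_at, r2$strategy$found_at)
  expect_identical(r1$trace, r2$trace)
})
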