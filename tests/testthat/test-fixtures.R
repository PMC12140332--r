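# Case registry, synthetic observations, configuration and trajectory I/O,
# and the command-line surface.

test_that("the registry exposes the thirteen benchmark cases with their unknown sets", {
  cases <- registered_cases()
  expect_gte(length(cases), 13)
  expect_setequal(
    names(cases),
    c(paste0("beam_case", 1:4), "beam_stvk",
      paste0("balloon_case", 1:4), paste0("valve_case", 1:4))
  )
  expect_equal(cases$beam_case4$unknowns, c("E_b", "E_a", "C", "W"))
  expect_equal(cases$balloon_case1$unknowns, "E_b")
  expect_equal(cases$beam_case1$truth_params$E_b, 1e3)
  expect_equal(cases$beam_case4$truth_params$E_a, 1e6)
  expect_equal(cases$balloon_case3$truth_params$R0, 41.2)
  expect_equal(cases$balloon_case3$truth_params$C2, -0.35)
  expect_equal(cases$valve_case2$truth_params$E_a * cases$valve_case2$truth_params$T_a,
               1e9 * 0.9)
  expect_equal(cases$beam_stvk$truth_model, "stvk")
  expect_error(get_case("no_such_case"), class = "lookup_error")
})

test_that("ground truths sit strictly inside the search bounds of every case", {
  for (case in registered_cases()) {
    for (nm in case$unknowns) {
      b <- case$bounds[[nm]]
      tr <- case$truth_params[[nm]]
      expect_gt(tr, b$lower)
      expect_lt(tr, b$upper)
    }
  }
})

test_that("every distinct benchmark configuration passes a forward smoke solve", {
  # beam cases 2-4 share one forward model; exercise each distinct truth
  for (nm in c("beam_case1", "beam_case4", "beam_stvk",
               "balloon_case1", "balloon_case4",
               "valve_case1", "valve_case4")) {
    obs <- generate_observation(nm)
    expect_true(all(is.finite(obs$D)))
    expect_gt(max(abs(obs$D)), 0)
    expect_true(all(obs$D[1, , ] == 0)) # step 0 is the undeformed state
  }
})

test_that("noise-free observations are seed-independent; noisy ones are seed-reproducible", {
  case <- get_case("beam_case1", "desk")
  o1 <- generate_observation(case, noise_sigma = 0, seed = 1)
  o2 <- generate_observation(case, noise_sigma = 0, seed = 999)
  expect_identical(o1$D, o2$D)
  n1 <- generate_observation(case, noise_sigma = 0.01, seed = 42)
  n2 <- generate_observation(case, noise_sigma = 0.01, seed = 42)
  n3 <- generate_observation(case, noise_sigma = 0.01, seed = 43)
  expect_identical(n1$D, n2$D)
  expect_false(identical(n1$D, n3$D))
  # noise magnitude is a fraction of the peak displacement
  expect_lt(max(abs(n1$D - o1$D)), 6 * 0.01 * max(abs(o1$D)))
})

test_that("trajectory CSV files round-trip through write and read", {
  case <- get_case("beam_case1", "desk")
  f <- tempfile(fileext = ".csv")
  obs <- generate_observation(case, noise_sigma = 0.01, seed = 7, file = f)
  back <- read_trajectory_csv(f)
  expect_equal(back$D, obs$D, tolerance = 1e-15)
  expect_equal(back$tracking$nodes, obs$tracking$nodes)
  expect_equal(back$meta$case, "beam_case1")
  expect_equal(back$meta$seed, "7") # noisy files record the seed
  # regenerating the noise-free file is byte-identical for any seed
  f1 <- tempfile(); f2 <- tempfile()
  generate_observation(case, 0, seed = 1, file = f1)
  generate_observation(case, 0, seed = 2, file = f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f, f1, f2))
})

test_that("case configuration JSON round-trips byte-identically", {
  cfg <- list(case = "beam_case4", mesh_preset = "desk",
              optimizer = list(q = 8, n0 = 10, budget = 80, seed = 1,
                               t_mode = "sampled", t_fixed = 2),
              noise_sigma = 0)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_case_config(cfg, f1)
  write_case_config(read_case_config(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  expect_error(read_case_config(tempfile()), class = "schema_error")
})

test_that("VTK export writes a parseable unstructured grid with region labels", {
  m <- label_elements(build_beam_mesh(c(2, 1, 1), c(2, 1, 1)),
                      brick_abnormality(1.5, 0.6))
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, displacement = matrix(0.5, nrow(m$nodes), 3))
  txt <- readLines(f)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 12 double", txt)))
  expect_true(any(grepl("^CELLS 2 18", txt)))
  expect_true(any(grepl("^SCALARS region int 1", txt)))
  expect_true(any(grepl("^VECTORS displacement double", txt)))
  regions <- as.integer(txt[(which(txt == "LOOKUP_TABLE default") + 1):(which(txt == "LOOKUP_TABLE default") + 2)])
  expect_equal(regions, c(0L, 1L))
  unlink(f)
})

test_that("the CLI lists cases, runs a forward solve, and fails cleanly", {
  out <- capture.output(code <- cli_main("list-cases"))
  expect_equal(code, 0L)
  expect_gte(length(out), 13)
  expect_true(any(grepl("beam_case4", out)))
  f <- tempfile(fileext = ".csv")
  code <- suppressMessages(cli_main(c("forward", "beam_case1", "-o", f)))
  expect_equal(code, 0L)
  tr <- read_trajectory_csv(f)
  expect_equal(dim(tr$D)[2], 4) # four long-edge keypoints
  expect_equal(dim(tr$D)[1], get_case("beam_case1")$load$n_steps + 1)
  unlink(f)
  expect_equal(cli_main(c("forward", "missing.json")), 1L)
  expect_equal(cli_main("not-a-command"), 2L)
})
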