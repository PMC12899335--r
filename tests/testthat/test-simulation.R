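test_that("simulate_trajectory produces floor(horizon/dt) + 1 positions", {
  rec <- simulate_trajectory("bird", "pigeon", horizon = 100, dt = 0.03,
                             seed = 1)
  expect_s3_class(rec, "trajectory_record")
  expect_equal(nrow(rec$positions), floor(100 / 0.03) + 1) # 3334
  expect_false(rec$is_drone)
  expect_equal(rec$species, "pigeon")

  # shortest admissible horizon: one step, two positions
  rec2 <- simulate_trajectory("drone", horizon = 0.03, dt = 0.03, seed = 1)
  expect_equal(nrow(rec2$positions), 2)
  expect_true(rec2$is_drone)

  expect_error(simulate_trajectory("bird", horizon = 0), "horizon")
  expect_error(simulate_trajectory("bird", dt = -1), "dt")
})

test_that("simulation is bit-reproducible per seed and varies across seeds", {
  a <- simulate_trajectory("bird", "gull", horizon = 10, seed = 7)
  b <- simulate_trajectory("bird", "gull", horizon = 10, seed = 7)
  c <- simulate_trajectory("bird", "gull", horizon = 10, seed = 8)
  expect_identical(a$positions, b$positions)
  expect_gt(max(abs(a$positions - c$positions)), 1)

  d1 <- simulate_trajectory("drone", horizon = 10, seed = 7)
  d2 <- simulate_trajectory("drone", horizon = 10, seed = 7)
  expect_identical(d1$positions, d2$positions)
})

test_that("JSON write/read round trip is bit-exact", {
  rec <- simulate_trajectory("bird", "peregrine", horizon = 5, seed = 3)
  path <- tempfile(fileext = ".json")
  write_trajectory_json(rec, path)
  back <- read_trajectory_json(path)
  expect_identical(back$positions, unname(rec$positions))
  expect_identical(back$is_drone, rec$is_drone)
  expect_identical(back$species, rec$species)
  expect_identical(back$dt, rec$dt)
  expect_identical(back$seed, rec$seed)
})

test_that("the JSON reader enforces the schema and tolerates extras", {
  p <- tempfile(fileext = ".json")

  # minimal valid file: label + movement history
  writeLines('{"is_drone": true, "movement_history": [[0,0,1],[0,0,2]]}', p)
  rec <- read_trajectory_json(p)
  expect_true(rec$is_drone)
  expect_equal(rec$positions, matrix(c(0, 0, 0, 0, 1, 2), 2))

  # unknown keys are ignored
  writeLines(paste0('{"is_drone": false, "operator": "x", "firmware": 3,',
                    '"movement_history": [[1,2,3]]}'), p)
  expect_false(read_trajectory_json(p)$is_drone)

  # missing movement_history is a parse error naming the key
  writeLines('{"is_drone": true}', p)
  expect_error(read_trajectory_json(p), "movement_history")

  # malformed coordinates
  writeLines('{"is_drone": true, "movement_history": [["a","b","c"]]}', p)
  expect_error(suppressWarnings(read_trajectory_json(p)),
               "movement_history")

  # missing label: error when required, NA when not
  writeLines('{"movement_history": [[0,0,1],[0,0,2]]}', p)
  expect_error(read_trajectory_json(p), "is_drone")
  rec <- read_trajectory_json(p, require_label = FALSE)
  expect_true(is.na(rec$is_drone))
})

test_that("downsample keeps endpoints, rescales dt and never upsamples", {
  pos <- cbind(seq_len(3334), 0, 0)
  rec <- trajectory_record(pos, is_drone = FALSE, dt = 0.03)
  d <- downsample(rec, 100)
  expect_equal(nrow(d$positions), 100)
  expect_equal(d$positions[1, ], rec$positions[1, ])
  expect_equal(d$positions[100, ], rec$positions[3334, ])
  expect_equal(d$dt, 0.03 * 3333 / 99)
  # indices stay strictly increasing (each kept point is distinct)
  expect_true(all(diff(d$positions[, 1]) > 0))

  short <- trajectory_record(cbind(1:50, 0, 0), is_drone = FALSE)
  expect_identical(downsample(short, 100)$positions, short$positions)
  expect_error(downsample(rec, 1), "target_len")
})

test_that("generate_dataset writes a balanced, reproducible dataset", {
  dir1 <- file.path(tempdir(), "ds-a")
  dir2 <- file.path(tempdir(), "ds-b")
  unlink(c(dir1, dir2), recursive = TRUE)
  m <- generate_dataset(3, dir1, seed = 21, horizon = 5)
  generate_dataset(3, dir2, seed = 21, horizon = 5)

  files <- list.files(dir1)
  expect_equal(sum(grepl("^bird_", files)), 3)
  expect_equal(sum(grepl("^drone_", files)), 3)
  expect_true("manifest.json" %in% files)
  # species cycle over the three presets
  expect_setequal(m$files$species[m$files$kind == "bird"],
                  c("pigeon", "gull", "peregrine"))

  # same seed -> byte-identical trajectory files
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  recs <- load_dataset(dir1)
  expect_length(recs, 6)
  labels <- vapply(recs, function(r) r$is_drone, logical(1))
  expect_equal(sum(labels), 3)
  expect_error(generate_dataset(0, dir1), "n_per_class")
})

test_that("trajectory_record validates positions", {
  expect_error(trajectory_record(matrix(numeric(0), ncol = 3), FALSE),
               "positions")
  expect_error(trajectory_record(matrix(c(1, 2, NA), 1), FALSE),
               "positions")
  r <- trajectory_record(matrix(1:6, 2), TRUE)
  expect_output(print(r), "drone")
})
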