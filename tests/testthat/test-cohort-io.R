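test_that("write/read round-trip is the identity at text precision", {
  co <- toy_cohort(n_per_group = 4)
  dir1 <- withr::local_tempdir()
  paths <- write_cohort(co, dir1)
  co2 <- read_cohort(paths["values"], paths["metadata"])
  expect_equal(co2$values, co$values, tolerance = 1e-9)
  expect_identical(co2$subjects$id, co$subjects$id)
  expect_identical(co2$subjects$group, co$subjects$group)
  # a second write of the re-read cohort is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- write_cohort(co2, dir2)
  expect_identical(readLines(paths2["values"]), readLines(paths["values"]))
})

test_that("reader rejects malformed value files with context", {
  co <- toy_cohort(n_per_group = 4)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)

  lines <- readLines(paths["values"])
  header <- strsplit(lines[1], ",")[[1]]
  header[3] <- header[2]                      # duplicate a region column
  writeLines(c(paste(header, collapse = ","), lines[-1]),
             file.path(dir, "dup.csv"))
  expect_error(read_cohort(file.path(dir, "dup.csv"), paths["metadata"]),
               "duplicated region")

  lines2 <- readLines(paths["values"])
  cells <- strsplit(lines2[2], ",")[[1]]
  cells[5] <- "not-a-number"
  writeLines(c(lines2[1], paste(cells, collapse = ","), lines2[-(1:2)]),
             file.path(dir, "bad.csv"))
  expect_error(read_cohort(file.path(dir, "bad.csv"), paths["metadata"]),
               "non-numeric value at row 1")

  expect_error(read_cohort(file.path(dir, "missing.csv"), paths["metadata"]),
               "not found")
})

test_that("subjects present in only one file are dropped with a warning", {
  co <- toy_cohort(n_per_group = 4)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  meta <- read.csv(paths["metadata"], stringsAsFactors = FALSE)
  meta_short <- meta[-3, ]
  write.csv(meta_short, file.path(dir, "meta_short.csv"), row.names = FALSE)
  expect_warning(
    co2 <- read_cohort(paths["values"], file.path(dir, "meta_short.csv")),
    "only one file")
  # set-difference oracle on the fixture ids
  expect_setequal(co2$subjects$id, setdiff(co$subjects$id,
                                           co$subjects$id[3]))
  expect_equal(n_subjects(co2), n_subjects(co) - 1L)
})

test_that("cohort validation enforces the invariants", {
  co <- toy_cohort(n_per_group = 4)
  bad <- co
  bad$values[1, 1] <- NaN
  expect_error(validate_cohort(bad), "non-finite")
  expect_error(write_cohort(bad, withr::local_tempdir()), "non-finite")

  bad2 <- co
  bad2$subjects$group[1] <- "A4?T?"
  expect_error(validate_cohort(bad2), "unknown group")

  bad3 <- co
  bad3$subjects$faq[2] <- 31
  expect_error(validate_cohort(bad3), "FAQ")

  bad4 <- co
  bad4$subjects$csf_ttau[1] <- 500    # subject 1 is in a T- group
  expect_error(validate_cohort(bad4), "cut-off")
})

test_that("an empty cohort writes header-only files", {
  atlas <- aal90_atlas()
  co <- tau_cohort(matrix(numeric(0), 0, 90,
                          dimnames = list(NULL, atlas$name)),
                   data.frame(id = character(0), group = character(0),
                              stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_length(readLines(paths["values"]), 1L)
  expect_length(readLines(paths["metadata"]), 1L)
})

test_that("split_by_group partitions disjointly, exhaustively and stably", {
  sim <- generate_cohort(simulation_config(seed = 7))
  by_g <- split_by_group(sim$cohort)
  sizes <- attr(by_g, "sizes")
  expect_equal(unname(sizes), c(103L, 34L, 44L, 44L))
  expect_equal(sum(sizes), n_subjects(sim$cohort))
  all_ids <- unlist(lapply(by_g, function(x) x$subjects$id))
  expect_setequal(all_ids, sim$cohort$subjects$id)
  expect_false(anyDuplicated(all_ids) > 0)

  # order invariance: shuffling subjects leaves partition contents unchanged
  set.seed(5)
  perm <- sample(n_subjects(sim$cohort))
  shuf <- tau_cohort(sim$cohort$values[perm, ],
                     sim$cohort$subjects[perm, ], sim$cohort$atlas)
  by_g2 <- split_by_group(shuf)
  for (g in names(by_g))
    expect_setequal(by_g2[[g]]$subjects$id, by_g[[g]]$subjects$id)

  single <- split_by_group(by_g[["A4+T+"]])
  expect_length(single, 1L)
  expect_identical(single[["A4+T+"]]$values, by_g[["A4+T+"]]$values)
})
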