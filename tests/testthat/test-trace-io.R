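# Manifest-driven reading and canonical writing of inertial traces.

test_that("manifests validate their fields and round-trip through YAML", {
  dir <- withr::local_tempdir()
  m <- dataset_manifest(dataset_id = "demo", fs_nominal = 200, unit_scale = 1,
                        axis_columns = list(x = "ax", y = "ay", z = "az"),
                        label_rule = list("^F" = "FALL", "^D" = "ADL"),
                        trace_glob = "*.csv", dir = dir)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m[c("dataset_id", "fs_nominal", "unit_scale", "axis_columns",
                       "label_rule", "trace_glob", "delimiter", "header")], path)
  m2 <- read_manifest(path)
  expect_s3_class(m2, "dataset_manifest")
  expect_equal(m2$fs_nominal, 200)
  expect_equal(m2$unit_scale, 1)
  expect_equal(m2$label_rule, m$label_rule)

  expect_fallcnn_error(
    dataset_manifest("x", fs_nominal = 0, trace_glob = "*"),
    "fallcnn_manifest_error", "fs_nominal")
  expect_fallcnn_error(
    dataset_manifest("x", fs_nominal = 10, unit_scale = -1),
    "fallcnn_manifest_error", "unit_scale")
  expect_fallcnn_error(
    dataset_manifest("x", fs_nominal = 10,
                     axis_columns = list(x = "a", y = "a", z = "b")),
    "fallcnn_manifest_error", "distinct")
  # missing required field is named in the error
  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(list(dataset_id = "x", fs_nominal = 10), bad)
  expect_fallcnn_error(read_manifest(bad), "fallcnn_manifest_error",
                       "unit_scale|axis_columns")
})

test_that("label rules resolve activity codes embedded in file names", {
  m <- dataset_manifest("x", fs_nominal = 200,
                        label_rule = list("D01" = "ADL", "F01" = "FALL"))
  expect_equal(resolve_label(m, "some/dir/F01_S1.txt"), "FALL")
  expect_equal(resolve_label(m, "D01_S2.txt"), "ADL")
  expect_fallcnn_error(resolve_label(m, "X99.txt"), "fallcnn_label_error")
  conflicted <- dataset_manifest("x", fs_nominal = 200,
                                 label_rule = list("S1" = "ADL", "F01" = "FALL"))
  expect_fallcnn_error(resolve_label(conflicted, "F01_S1.txt"),
                       "fallcnn_label_error", "conflict")
})

test_that("read_trace applies the unit scale and selects configured columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "F01.csv")
  writeLines(c("ax,ay,az", "0,0,1", "0,1,0", "1,0,0"), path)
  m <- dataset_manifest("x", fs_nominal = 200, unit_scale = 9.81,
                        label_rule = list("F" = "FALL"))
  tr <- read_trace(path, m)
  expect_s3_class(tr, "inertial_trace")
  expect_equal(n_samples(tr), 3L)
  expect_equal(unname(tr$samples[1, ]), c(0, 0, 9.81))
  expect_equal(tr$label, "FALL")
  expect_equal(tr$fs, 200)

  # 4-column file, axes in columns 2-4; oracle = hand-read values
  path4 <- file.path(dir, "F02.csv")
  writeLines(c("t,c2,c3,c4", "0.0,1.5,2.5,3.5", "0.1,4.5,5.5,6.5"), path4)
  m4 <- dataset_manifest("x", fs_nominal = 50, unit_scale = 2,
                         axis_columns = list(x = "c2", y = "c3", z = "c4"),
                         label_rule = list("F" = "FALL"))
  tr4 <- read_trace(path4, m4)
  expect_equal(unname(tr4$samples),
               2 * matrix(c(1.5, 4.5, 2.5, 5.5, 3.5, 6.5), 2, 3))
  # same file via 1-based column indices
  m4i <- dataset_manifest("x", fs_nominal = 50, unit_scale = 2,
                          axis_columns = list(x = 2, y = 3, z = 4),
                          label_rule = list("F" = "FALL"))
  expect_equal(read_trace(path4, m4i)$samples, tr4$samples)
})

test_that("read_trace reports format, parse and empty-file errors precisely", {
  dir <- withr::local_tempdir()
  m <- dataset_manifest("x", fs_nominal = 100, label_rule = list("." = "ADL"))
  p1 <- file.path(dir, "missingcol.csv")
  writeLines(c("ax,ay", "1,2"), p1)
  expect_fallcnn_error(read_trace(p1, m), "fallcnn_format_error", "az")
  p2 <- file.path(dir, "badcell.csv")
  writeLines(c("ax,ay,az", "1,2,3", "1,oops,3"), p2)
  expect_fallcnn_error(read_trace(p2, m), "fallcnn_parse_error", "row 2")
  p3 <- file.path(dir, "empty.csv")
  writeLines("ax,ay,az", p3)
  expect_fallcnn_error(read_trace(p3, m), "fallcnn_empty_trace")
})

test_that("write/read round-trip preserves values, order and metadata", {
  dir <- withr::local_tempdir()
  tr <- fallcnn:::with_seed(4, {
    inertial_trace(matrix(stats::rnorm(300, 0, 15), 100, 3), fs = 128,
                   label = "FALL", subject_id = "S7", activity_code = "F03",
                   dataset_id = "demo")
  })
  path <- file.path(dir, "FALL_rt.csv")
  write_trace(tr, path)
  m <- dataset_manifest("demo", fs_nominal = 128, unit_scale = 1,
                        label_rule = list("^FALL" = "FALL"), dir = dir)
  back <- read_trace(path, m)
  expect_equal(n_samples(back), 100L)
  expect_lt(max(abs(back$samples - tr$samples)), 1e-9)
  expect_equal(back$label, "FALL")         # sidecar metadata preserved
  expect_equal(back$subject_id, "S7")
  expect_equal(back$activity_code, "F03")
  # sidecar alone can resolve the label when no rule matches
  m_norule <- dataset_manifest("demo", fs_nominal = 128,
                               label_rule = list("ZZZ" = "ADL"), dir = dir)
  expect_equal(read_trace(path, m_norule)$label, "FALL")
})

test_that("trace invariants are enforced at construction", {
  expect_fallcnn_error(inertial_trace(matrix(numeric(0), 0, 3), 100, "ADL"),
                       "fallcnn_invalid_trace")
  expect_fallcnn_error(inertial_trace(matrix(c(1, 2, NA), 1, 3), 100, "ADL"),
                       "fallcnn_invalid_trace")
  expect_fallcnn_error(inertial_trace(matrix(1, 1, 3), -5, "ADL"),
                       "fallcnn_invalid_trace")
  expect_fallcnn_error(inertial_trace(matrix(1, 1, 3), 100, "WALK"),
                       "fallcnn_invalid_trace")
})
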