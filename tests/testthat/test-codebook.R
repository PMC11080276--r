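test_that("default codebook reproduces the study coding scheme", {
  cb <- default_codebook()
  expect_length(cb$variables, 27L)
  kinds <- vapply(cb$variables, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "categorical"), 17L)
  expect_identical(sum(kinds == "continuous"), 10L)

  sex <- cb$variables$sex
  expect_identical(sex$states, c(male = 1L, female = 2L))
  expect_identical(sex$reference, 1L)
  expect_identical(cb$variables$area$states,
                   c(rural = 1L, suburban = 2L, urban = 3L))
  expect_identical(cb$variables$fhx_dm$states, c(no = 0L, yes = 1L))
  expect_identical(cb$variables$smoke$states,
                   c(never = 1L, occasionally = 2L, often = 3L, quitting = 4L))
  expect_identical(cb$variables$occupation$reference, 1L)
  # every categorical reference level is a declared state
  for (v in cb$variables[kinds == "categorical"])
    expect_true(v$reference %in% v$states)

  expect_identical(cb$variables$sbp$cutpoints, 140)
  expect_identical(cb$variables$sbp$bin_codes, 0:1)
  expect_identical(cb$variables$dbp$cutpoints, 90)
  expect_identical(cb$variables$age$cutpoints, c(45, 60))
  expect_identical(cb$variables$bmi$cutpoints, c(18.5, 24, 28))
  expect_identical(cb$variables$fbg$cutpoints, 7.0)
  expect_identical(cb$variables$tg$cutpoints, 2.3)
  expect_identical(cb$variables$tc$cutpoints, 6.2)
  expect_identical(cb$variables$hdl$cutpoints, 2.3)
  # the reversed lipid rule: low LDL-C is the flagged code
  expect_identical(cb$variables$ldl$bin_codes, c(1L, 0L))

  # diagnostic-criterion exclusion for the diabetes outcome
  expect_identical(cb$exclusions$T2DM, "fbg")
  expect_setequal(cb$outcomes, c("T2DM", "CAD", "comorbidity"))
})

test_that("variable_spec rejects malformed declarations", {
  expect_error(variable_spec("x", "continuous", cutpoints = c(90, 60),
                             bin_codes = 1:3), "increasing")
  expect_error(variable_spec("x", "categorical",
                             states = c(a = 1, b = 1)), "duplicate")
  expect_error(variable_spec("x", "categorical", states = c(a = 1, b = 2),
                             reference = 3), "reference")
  expect_error(variable_spec("x", "continuous", cutpoints = 1,
                             bin_codes = 1:3), "bin code")
  expect_error(codebook(list(variable_spec("a", "categorical",
                                           states = c(x = 1, y = 2)),
                             variable_spec("a", "categorical",
                                           states = c(x = 1, y = 2)))),
               "duplicate variable name")
})

test_that("load_codebook round-trips a YAML declaration", {
  cfg <- list(variables = list(
    sex = list(kind = "categorical", states = list(male = 1, female = 2),
               reference = 1),
    sbp = list(kind = "continuous", cutpoints = 140, bin_codes = c(0, 1),
               units = "mmHg")),
    outcomes = list("T2DM"))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  cb <- load_codebook(path)
  expect_identical(cb$variables$sex$states, c(male = 1L, female = 2L))
  expect_identical(cb$variables$sbp$cutpoints, 140)
  expect_identical(cb$outcomes, "T2DM")
})

test_that("encoding maps labels to codes and rejects unknown labels", {
  cb <- default_codebook()
  raw <- data.frame(group = c("control", "T2DM", "control"),
                    sex = c("female", "male", "female"),
                    age = c(40, 61, 35.5),
                    stringsAsFactors = FALSE)
  enc <- encode_dataset(raw, cb)
  expect_identical(enc$sex, c(2L, 1L, 2L))
  expect_identical(enc$age, c(40, 61, 35.5))
  expect_identical(nrow(enc), 3L)

  empty <- raw[0, ]
  expect_identical(nrow(encode_dataset(empty, cb)), 0L)
  expect_named(encode_dataset(empty, cb), names(raw))

  raw$sex[2] <- "malee"
  expect_error(encode_dataset(raw, cb), "malee.*sex.*row 2|'malee' in column 'sex' \\(row 2\\)")
  expect_error(encode_dataset(data.frame(sex = "male"), cb), "group")
})

test_that("encoding then decoding labels is the identity on all states", {
  cb <- default_codebook()
  for (nm in names(cb$variables)) {
    spec <- cb$variables[[nm]]
    if (spec$kind != "categorical") next
    raw <- data.frame(group = rep("control", length(spec$states)),
                      x = names(spec$states), stringsAsFactors = FALSE)
    names(raw)[2] <- nm
    enc <- encode_dataset(raw, cb)
    expect_identical(names(spec$states)[match(enc[[nm]], spec$states)],
                     names(spec$states), info = nm)
  }
})

test_that("discretization matches the published bin boundaries", {
  cb <- default_codebook()
  d <- function(nm, x) {
    tab <- data.frame(group = "control", v = x)
    names(tab)[2] <- nm
    discretize(tab, cb)[[nm]]
  }
  expect_identical(d("age", c(44, 45, 59, 60, 80)), c(1L, 2L, 2L, 3L, 3L))
  expect_identical(d("heart_rate", c(59, 60, 100, 101)), c(1L, 2L, 2L, 3L))
  expect_identical(d("bmi", c(18.49, 18.5, 23.995, 24.0, 27.99, 28.0)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_identical(d("sbp", c(139.9, 140)), c(0L, 1L))
  expect_identical(d("ldl", c(0.9, 1.0, 3.2)), c(1L, 0L, 0L))
  expect_identical(d("fbg", c(6.99, 7.0)), c(0L, 1L))
})

test_that("discretization is total and idempotent on random inputs", {
  cb <- default_codebook()
  set.seed(11)
  for (nm in c("age", "bmi", "heart_rate", "ldl", "tc")) {
    spec <- cb$variables[[nm]]
    x <- c(stats::runif(500, -10, 300), spec$cutpoints,
           spec$cutpoints - 1e-9, spec$cutpoints + 1e-9)
    tab <- data.frame(group = "g", v = x)
    names(tab)[2] <- nm
    once <- discretize(tab, cb)
    expect_true(all(once[[nm]] %in% spec$bin_codes), info = nm)
    expect_false(anyNA(once[[nm]]), info = nm)
  }
})

test_that("cohort CSV round-trips losslessly and flags ragged rows", {
  tab <- data.frame(group = c("control", "T2DM", "control"),
                    sex = c(1L, 2L, 2L), age = c(40.5, 61.25, 35),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  expect_identical(back$group, tab$group)
  expect_identical(back$sex, tab$sex)
  expect_identical(back$age, tab$age)

  writeLines(c("a,b", "1,2", "1,2,3"), path)
  expect_error(read_cohort_csv(path), "line 3")
  expect_error(read_cohort_csv(tempfile()), "no such file")
})

test_that("a full generated cohort survives the CSV round trip", {
  coh <- generate_case_control(reference_profiles(), seed = 7)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_identical(nrow(back), 3824L)
  expect_identical(table(back$group), table(coh$group))
  expect_equal(back$age, coh$age)
})

test_that("network JSON round-trips and DOT export lists every arc", {
  net <- toy_net_2()
  path <- tempfile(fileext = ".json")
  write_bn_json(net, path)
  net2 <- read_bn_json(path)
  expect_identical(names(net2$nodes), names(net$nodes))
  expect_equal(net2$nodes$D$cpt, net$nodes$D$cpt)
  expect_identical(net2$nodes$D$parents, "A")

  # a 17-node, 21-edge structure exports 21 arcs
  set.seed(5)
  nodes <- paste0("n", 1:17)
  edges <- list()
  while (length(edges) < 21) {
    ft <- sort(sample(17, 2))
    key <- paste(ft, collapse = "-")
    if (!key %in% names(edges))
      edges[[key]] <- data.frame(from = nodes[ft[1]], to = nodes[ft[2]])
  }
  g <- dag(nodes, do.call(rbind, edges))
  dot <- export_dot(g)
  expect_identical(lengths(regmatches(dot, gregexpr("->", dot))), 21L)

  # malformed CPT length must be rejected
  bad <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad$nodes[[2]]$cpt <- list(0.2, 0.3, 0.5)
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_bn_json(path2), "length|dimension")
})
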