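test_that("template generators match the golden dialect transcriptions", {
  for (dialect in c("monaco_vmat_single", "monaco_vmat_sib", "pinnacle_imrt")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    serialize_template(build_template(dialect), f)
    expect_identical(readLines(f, encoding = "UTF-8"),
                     readLines(golden_template_path(dialect), encoding = "UTF-8"),
                     info = dialect)
  }
})

test_that("constraint fields carry the printed planning constants", {
  single <- build_template("monaco_vmat_single", n = 45)
  expect_equal(template_functions(single, "Ring 43")$ref_cgy, 4400)
  expect_equal(template_functions(single, "Ring 43")$cost, "overdose_dvh")
  expect_equal(template_functions(single, "Ring 45")$iso, 4500)
  expect_equal(template_functions(single, "Ring 45")$weight, 10)
  expect_equal(template_functions(single, "Body")$iso, 5000)
  sib <- build_template("monaco_vmat_sib", n = 50)
  expect_equal(template_functions(sib, "Ring 50", "underdose_dvh")$iso, 96.5)
  expect_equal(template_functions(sib, "Ring 50", "underdose_dvh")$ref_cgy, 5000)
  expect_equal(template_functions(sib, "Ring 45", "underdose_dvh")$iso, 98.5)
  expect_equal(template_functions(sib, "Ring 50", "maximum_dose")$iso, 5500)
  expect_equal(template_functions(sib, "Body")$iso, 5500)
  imrt <- build_template("pinnacle_imrt", n = 45, organs = c("bladder", "rectum"))
  expect_equal(template_functions(imrt, "Ring 45", "minimum_dose")$ref_cgy, 4500)
  expect_equal(template_functions(imrt, "Ring 45", "maximum_dose")$ref_cgy, 4650)
  expect_equal(template_functions(imrt, "Ring 45", "min_dvh")$iso, 100)
  expect_equal(template_functions(imrt, "Ring 45", "uniform_dose")$ref_cgy, 4550)
  expect_equal(template_functions(imrt, ring_organ_name(30, "bladder"))$ref_cgy, 3000)
  expect_equal(template_functions(imrt, ring_organ_name(39, "rectum"))$ref_cgy, 3900)
})

test_that("the ring reference-dose progression is affine and stops at ring 25", {
  for (dialect in c("monaco_vmat_single", "monaco_vmat_sib", "pinnacle_imrt")) {
    tpl <- build_template(dialect)
    for (k in 25:44) {
      row <- template_functions(tpl, ring_name <- sprintf("Ring %d", k))
      row <- row[row$cost %in% c("overdose_dvh", "maximum_dose"), ]
      expect_equal(row$ref_cgy[1], (k + 1) * 100, info = sprintf("%s k=%d", dialect, k))
      expect_equal(row$weight[1], 0.01)
    }
    expect_equal(nrow(template_functions(tpl, "Ring 24")), 0)
  }
})

test_that("serialization round-trips and rejects malformed inputs", {
  tpl <- build_template("monaco_vmat_sib")
  f <- withr::local_tempfile(fileext = ".tsv")
  serialize_template(tpl, f)
  back <- parse_template(f)
  expect_identical(back$functions, tpl$functions)
  expect_identical(back$dialect, tpl$dialect)
  expect_identical(back$n, tpl$n)
  # malformed row reports its line number
  lines <- readLines(f, encoding = "UTF-8")
  lines[8] <- "Ring 45\tbroken"
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, f2, useBytes = TRUE)
  expect_error(parse_template(f2), "line 8")
  # unknown cost types are rejected too
  lines2 <- readLines(f, encoding = "UTF-8")
  lines2[7] <- "Ring 50\tnot_a_cost\t1\t-\t5000"
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines2, f3, useBytes = TRUE)
  expect_error(parse_template(f3), "line 7")
  # empty templates cannot be serialized
  empty <- tpl
  empty$functions <- tpl$functions[0, ]
  expect_error(serialize_template(empty, withr::local_tempfile()), "empty")
})

test_that("objective penalties follow the quadratic-hinge definitions", {
  geo <- toy_geometry(c(5, 4, 1), spacing = c(3, 3, 3))
  all_mask <- binary_mask(array(1, dim = geo$shape), geo)
  st <- structure_set(list(S = all_mask))
  mk_tpl <- function(rows) {
    structure(list(dialect = "monaco_vmat_single", n = 45L, min_level = 25L,
                   organs = "organ", functions = rows),
              class = "constraint_template")
  }
  # 20-voxel structure with exactly one voxel (5%) above the reference
  vals <- array(40, dim = geo$shape)
  vals[1, 1, 1] <- 46
  dose <- dose_grid(vals, geo)
  tpl <- mk_tpl(doserings:::cf_row("S", "overdose_dvh", 2, ref_cgy = 4500, iso = 0.01))
  out <- evaluate_objective(dose, tpl, st)
  expect_equal(out$per_function$penalty, (5 - 0.01)^2)
  expect_equal(out$total, 2 * (5 - 0.01)^2)
  # doses below every maximum-dose bound contribute nothing
  tpl2 <- mk_tpl(doserings:::cf_row("S", "maximum_dose", 5, ref_cgy = 5000))
  expect_equal(evaluate_objective(dose, tpl2, st)$total, 0)
  # weight linearity: doubling the weight doubles the contribution
  tpl3a <- mk_tpl(doserings:::cf_row("S", "minimum_dose", 1, ref_cgy = 4500))
  tpl3b <- mk_tpl(doserings:::cf_row("S", "minimum_dose", 2, ref_cgy = 4500))
  expect_equal(2 * evaluate_objective(dose, tpl3a, st)$total,
               evaluate_objective(dose, tpl3b, st)$total)
  # underdose bound: coverage above the 96.5% isoconstraint costs nothing,
  # below it the squared shortfall is charged
  vals2 <- array(51, dim = c(5, 4, 1))
  tpl4 <- mk_tpl(doserings:::cf_row("S", "underdose_dvh", 100, ref_cgy = 5000,
                                    iso = 96.50))
  expect_equal(evaluate_objective(dose_grid(vals2, geo), tpl4, st)$total, 0)
  vals2[1, 1, 1] <- 1   # 19/20 = 95% coverage -> shortfall 1.5 points
  out4 <- evaluate_objective(dose_grid(vals2, geo), tpl4, st)
  expect_equal(out4$total, 100 * (96.5 - 95)^2)
  # unresolved structures are listed by name
  tpl5 <- mk_tpl(doserings:::cf_row("Ring 7 ∩ rectum", "maximum_dose", 1,
                                    ref_cgy = 700))
  expect_error(evaluate_objective(dose, tpl5, st), "Ring 7 ∩ rectum")
})

test_that("monaco-style rows use the isoconstraint as the dose bound", {
  geo <- toy_geometry(c(4, 4, 1))
  st <- structure_set(list(Body = binary_mask(array(1, geo$shape), geo)))
  dose <- dose_grid(array(52, dim = geo$shape), geo)
  tpl <- structure(list(dialect = "monaco_vmat_single", n = 45L, min_level = 25L,
                        organs = "organ",
                        functions = doserings:::cf_row("Body", "maximum_dose", 1,
                                                       iso = 5000)),
                   class = "constraint_template")
  # 52 Gy against the 50 Gy cap -> mean hinge (52-50)^2 = 4
  expect_equal(evaluate_objective(dose, tpl, st)$total, 4)
})
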