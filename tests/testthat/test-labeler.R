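test_that("the default criteria table carries all twelve clinical rows", {
  cr <- default_criteria()
  expect_equal(nrow(cr), 12)
  rectum_dmax <- cr[cr$structure == "Rectum" & cr$metric == "Dmax", ]
  expect_equal(rectum_dmax$comparator, "<")
  expect_equal(rectum_dmax$limit, 40)
  expect_equal(rectum_dmax$tolerance, 0)
  expect_equal(rectum_dmax$unit, "Gy")
  bl <- cr[cr$structure == "Bladder" & cr$metric == "V37Gy", ]
  expect_equal(bl$limit, 10); expect_equal(bl$tolerance, 0.5)
  expect_equal(bl$unit, "cc")
  ur <- cr[cr$structure == "Urethra", ]
  expect_equal(ur$limit, 41); expect_equal(ur$tolerance, 1.5)
  ctv <- cr[cr$structure == "CTV4000", ]
  expect_equal(ctv$comparator, ">"); expect_equal(ctv$tolerance, -5)
})

# a DVH table strictly inside every limit
all_pass_dvh <- function() {
  data.frame(
    structure = c("CTV4000", "PTV", "PTV", "Rectum", "Rectum", "Rectum",
                  "Rectum", "Bladder", "Bladder", "Femur R", "Femur L",
                  "Urethra"),
    metric = c("V40Gy", "V36.25Gy", "V34.40Gy", "Dmax", "V38Gy", "V36Gy",
               "V29Gy", "V37Gy", "V18.1Gy", "V14.5Gy", "V14.5Gy", "D50%"),
    value = c(97, 97.5, 99, 37, 0.05, 0.5, 15, 6, 35, 1.5, 1.5, 39),
    unit = c("%", "%", "%", "Gy", "cc", "cc", "%", "cc", "%", "%", "%",
             "Gy"),
    stringsAsFactors = FALSE)
}

test_that("rule application distinguishes strict, tolerated and violated values", {
  ev <- evaluate_plan(all_pass_dvh())
  expect_true(ev$acceptable)
  expect_true(all(ev$results$status == "pass_strict"))

  # rectum D_max 41 Gy against < 40 Gy with zero tolerance: violated
  d1 <- all_pass_dvh(); d1$value[d1$metric == "Dmax"] <- 41
  ev1 <- evaluate_plan(d1)
  expect_false(ev1$acceptable)
  expect_equal(ev1$results$status[ev1$results$metric == "Dmax"], "violated")

  # PTV coverage 91% against > 95% with -5% tolerance: within tolerance
  d2 <- all_pass_dvh(); d2$value[d2$metric == "V36.25Gy"] <- 91
  ev2 <- evaluate_plan(d2)
  expect_true(ev2$acceptable)
  expect_equal(ev2$results$status[ev2$results$metric == "V36.25Gy"],
               "pass_within_tolerance")

  # boundary semantics: exactly at the relaxed limit counts as violated
  d3 <- all_pass_dvh(); d3$value[d3$metric == "V37Gy"] <- 10.5
  ev3 <- evaluate_plan(d3)
  expect_equal(ev3$results$status[ev3$results$metric == "V37Gy"], "violated")
  d4 <- all_pass_dvh(); d4$value[d4$metric == "V37Gy"] <- 10.49
  expect_equal(evaluate_plan(d4)$results$status[
    evaluate_plan(d4)$results$metric == "V37Gy"], "pass_within_tolerance")

  # a zero tolerance makes pass_within_tolerance unreachable
  d5 <- all_pass_dvh(); d5$value[d5$metric == "Dmax"] <- 40
  expect_equal(evaluate_plan(d5)$results$status[
    evaluate_plan(d5)$results$metric == "Dmax"], "violated")

  d6 <- all_pass_dvh()[-4, ]
  expect_error(evaluate_plan(d6), "Rectum Dmax")
})

test_that("strategy determination follows the ATP-acceptable rule with a both-fail flag", {
  ok <- all_pass_dvh()
  bad <- all_pass_dvh(); bad$value[bad$metric == "Dmax"] <- 42

  expect_identical(determine_strategy(ok, ok)$label, "ATP")
  d <- determine_strategy(bad, ok)
  expect_identical(d$label, "ATS")
  expect_false(d$flagged)
  both <- determine_strategy(bad, bad)
  expect_identical(both$label, "ATS")
  expect_true(both$flagged)
})

test_that("worsening any single ATP metric never flips ATS back to ATP", {
  set.seed(61)
  cr <- default_criteria()
  ok <- all_pass_dvh()
  for (i in 1:30) {
    base <- ok
    # random degradation of one or more metrics
    k <- sample(nrow(base), sample(3, 1))
    for (j in k) {
      worse <- if (cr$comparator[j] == "<") runif(1, 0, 30) else
        -runif(1, 0, 30)
      base$value[j] <- max(base$value[j] + worse, 0)
    }
    lab1 <- determine_strategy(base, ok)$label
    # degrade one more metric further
    j2 <- sample(nrow(base), 1)
    base2 <- base
    base2$value[j2] <- max(base2$value[j2] +
                             if (cr$comparator[j2] == "<") 10 else -10, 0)
    lab2 <- determine_strategy(base2, ok)$label
    expect_false(lab1 == "ATS" && lab2 == "ATP")
  }
})

test_that("criteria round-trip through the YAML schema", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(default_criteria(), f)
  back <- read_criteria(f)
  expect_equal(back, default_criteria())

  shipped <- system.file("extdata", "dosimetric_criteria.yaml",
                         package = "mrgadapt")
  expect_equal(read_criteria(shipped), default_criteria())

  bad <- default_criteria()
  bad$tolerance[4] <- -1   # "<" criterion must not relax downward
  expect_error(write_criteria(bad, f), "inconsistent")
})
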