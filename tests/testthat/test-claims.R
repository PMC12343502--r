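test_that("claim lines sharing (patient, date, provider) collapse into one visit with summed expense", {
  path <- write_claims_fixture(c(
    claims_header,
    "p1,2016-03-01,H1,I10,10,employee",
    "p1,2016-03-01,H1,I10,20,employee",
    "p1,2016-03-01,H1,I10,5,employee",
    "p1,2016-03-02,H2,i10.x02,7.5,employee"))
  v <- read_claims(path)
  expect_equal(nrow(v), 2L)
  expect_equal(v$expense[v$visit_date == as.Date("2016-03-01")], 35)
  # total expense conserved across collapsing
  expect_equal(sum(v$expense), 42.5)
  # normalization: uppercase, dot stripped
  expect_equal(v$primary_dx[v$visit_date == as.Date("2016-03-02")], "I10X02")
})

test_that("schema violations and bad rows are reported as configured", {
  path <- write_claims_fixture(c(
    "patient_id,visit_date,primary_dx,expense,insurance_type",
    "p1,2016-03-01,I10,10,employee"))
  expect_error(read_claims(path), "provider_id")

  bad <- write_claims_fixture(c(
    claims_header,
    "p1,2016-03-01,H1,I10,10,employee",
    "p1,not-a-date,H1,I10,10,employee"))
  expect_error(read_claims(bad), "line")
  v <- suppressWarnings(
    read_claims(bad, claims_schema(tolerate_bad_rows = TRUE)))
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_bad_rows"), 1L)
})

test_that("hypertension identification matches the ICD-10 prefix rule", {
  expect_true(is_hypertension_case("I10X02"))
  expect_true(is_hypertension_case(c("E11", "I159")))
  expect_false(is_hypertension_case(c("I20", "E11")))
  expect_false(is_hypertension_case(character(0)))
  expect_true(is_hypertension_case("i11.9"))
})

test_that("panels cover the full horizon and partition in-window visits", {
  lines <- c(claims_header,
             "p1,2016-02-01,H1,I10,10,resident",
             "p1,2016-02-11,H1,I10,10,resident",
             "p1,2021-05-01,H2,I10,12,resident",
             "p1,2015-12-31,H1,I10,99,resident",   # outside window
             sprintf("p2,2018-%02d-01,%s,I10,5,employee", 1:10,
                     rep(c("H1", "H2"), c(7, 3))))
  v <- read_claims(write_claims_fixture(lines))
  panels <- build_panels(v, baseline_year = 2016, horizon = 6)
  expect_equal(attr(panels, "n_visits_outside_window"), 1L)
  y1 <- panels$years[panels$years$patient_id == "p1", ]
  expect_equal(nrow(y1), 6L)
  expect_equal(sum(y1$n_visits == 0), 4L)
  # 10 visits in 2018 across providers 7/3
  y2 <- panels$years[panels$years$patient_id == "p2" & panels$years$t == 2, ]
  expect_equal(y2$n_visits, 10L)
  expect_equal(sort(unname(y2$providers[[1]])), c(3L, 7L))
  # visits partition across panel-years
  expect_equal(sum(panels$years$n_visits), nrow(v) - 1L)
  # empty input gives no panels
  expect_equal(n_patients(build_panels(v[0, ], baseline_year = 2016)), 0L)
})

test_that("cohort filter applies age, qualifying-years and diagnosis rules", {
  mk_panel <- function(id, yearly_n, dx = "I10", birth = "1960-06-01") {
    rows <- character(0)
    for (t in seq_along(yearly_n)) {
      n <- yearly_n[t]
      if (n > 0) {
        rows <- c(rows, sprintf("%s,%d-%02d-01,H%d,%s,10,resident",
                                id, 2015 + t, 1:n * 0 + pmin(t, 12), 1:n, dx))
      }
    }
    rows
  }
  lines <- c(claims_header,
             mk_panel("keep", c(5, 4, 3, 2, 1, 0)),
             mk_panel("fewyears", c(5, 4, 1, 1, 1, 1)),
             mk_panel("nohtn", c(5, 4, 3, 0, 0, 0), dx = "E11"),
             mk_panel("young", c(5, 4, 3, 0, 0, 0), birth = "2005-06-01"))
  # distinct dates within each year to avoid collapse
  lines <- unique(lines)
  v <- read_claims(write_claims_fixture(lines))
  demo <- tibble::tibble(
    patient_id = c("keep", "fewyears", "nohtn", "young"),
    sex = "female",
    birth_date = as.Date(c("1960-06-01", "1960-06-01", "1960-06-01",
                           "2005-06-01")),
    insurance_type = "resident")
  panels <- build_panels(v, demo, baseline_year = 2016, horizon = 6)
  kept <- cohort_filter(panels)
  disp <- attr(kept, "disposition")
  expect_setequal(kept$patients$patient_id, "keep")
  expect_equal(disp$reason[disp$patient_id == "fewyears"],
               "too_few_qualifying_years")
  expect_equal(disp$reason[disp$patient_id == "nohtn"], "not_hypertension")
  expect_equal(disp$reason[disp$patient_id == "young"], "underage")
  # idempotent
  again <- cohort_filter(kept)
  expect_equal(n_patients(again), n_patients(kept))
  expect_equal(nrow(attr(again, "disposition")), 0L)
})
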