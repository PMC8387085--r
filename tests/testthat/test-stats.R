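test_that("patient aggregation averages fields and passes through otherwise", {
  tab <- make_field_table()
  pat <- aggregate_units(tab, "patient")
  expect_equal(nrow(pat), 4L)
  expect_equal(pat$area[pat$sample_id == "a1"], mean(c(6, 7, 8)))
  # idempotence: identical fields aggregate to the field value
  same <- tab; same$area <- 5
  expect_true(all(aggregate_units(same, "patient")$area == 5))
  # pass-through at field level
  expect_equal(nrow(aggregate_units(tab, "field")), 12L)
  # empty fields and all-empty patients are excluded
  tab2 <- tab; tab2$n_roi[tab2$sample_id == "a1"] <- 0L
  expect_warning(pat2 <- aggregate_units(tab2, "patient"), "empty field")
  expect_false("a1" %in% pat2$sample_id)
})

test_that("identical groups give t = 0 and p = 1", {
  tab <- data.frame(sample_id = letters[1:6],
                    group_label = rep(c("disease", "control"), each = 3),
                    area = c(1, 2, 3, 1, 2, 3))
  cmp <- compare_groups(tab, "area")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("perfect separation with zero variance is flagged, p near zero", {
  tab <- data.frame(sample_id = letters[1:8],
                    group_label = rep(c("disease", "control"), each = 4),
                    area = c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_warning(cmp <- compare_groups(tab, "area"), "degenerate")
  expect_true(is.infinite(cmp$t_statistic))
  expect_gt(cmp$p_value, 0)
  expect_lt(cmp$p_value, 1e-100)
})

test_that("the pooled t-test matches the textbook formula", {
  x <- c(2.1, 2.4, 2.9, 3.1, 2.6)
  y <- c(2.8, 3.0, 2.9, 3.2, 3.3, 2.7, 3.1)
  tab <- data.frame(sample_id = paste0("s", 1:12),
                    group_label = rep(c("disease", "control"), c(5, 7)),
                    area = c(x, y))
  cmp <- compare_groups(tab, "area")
  ora <- oracle_pooled_t(x, y)
  expect_equal(cmp$t_statistic, ora$t, tolerance = 1e-12)
  expect_equal(cmp$df, ora$df)
  expect_equal(cmp$p_value, ora$p, tolerance = 1e-12)
  expect_equal(cmp$group_a_mean, mean(x))
  expect_equal(cmp$group_a_sd, sd(x))       # sample SD, n-1 denominator
  expect_equal(cmp$group_a_n, 5)
})

test_that("swapping the groups negates t and preserves p", {
  tab <- make_field_table()
  pat <- aggregate_units(tab)
  cmp <- compare_groups(pat, "pf_ratio")
  swapped <- pat
  swapped$group_label <- ifelse(pat$group_label == "disease",
                                "control", "disease")
  cmp2 <- compare_groups(swapped, "pf_ratio")
  expect_equal(cmp2$t_statistic, -cmp$t_statistic)
  expect_equal(cmp2$p_value, cmp$p_value)
})

test_that("groups of one unit get descriptives without a test", {
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    group_label = c("disease", "control", "control"),
                    area = c(5, 6, 7))
  expect_warning(cmp <- compare_groups(tab, "area"), "fewer than 2")
  expect_equal(cmp$group_a_mean, 5)
  expect_true(is.na(cmp$group_a_sd))
  expect_true(is.na(cmp$t_statistic))
  expect_true(is.na(cmp$p_value))
})

test_that("subgroup tables are descriptive only, SD missing at n = 1", {
  pat <- aggregate_units(make_field_table())
  sub <- subgroup_table(pat, "area")
  # totals plus per-subgroup rows, no test columns anywhere
  expect_false(any(grepl("p_value|t_", names(sub))))
  dis_total <- sub[sub$group_label == "disease" & sub$subgroup == "total", ]
  expect_equal(dis_total$n, 2)
  cld <- sub[sub$subgroup == "clinical_liver_disease", ]
  expect_equal(cld$n, 1)
  expect_true(is.na(cld$sd))
  expect_false(is.na(cld$mean))
  # no subgroup labels -> only total rows
  pat2 <- pat; pat2$subgroup <- NULL
  sub2 <- subgroup_table(pat2, "area")
  expect_setequal(unique(sub2$subgroup), c("total", "none"))
  wide <- format_report_table(sub, compare_groups(pat, "area"))
  expect_true("p_value" %in% names(wide))
  expect_equal(nrow(wide), 1L)
})
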