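events_tbl <- function(pairs) {
  tibble::tibble(initiator_id = vapply(pairs, `[`, "", 1L),
                 target_id = vapply(pairs, `[`, "", 2L))
}

test_that("interaction categorization follows participant groups", {
  ros <- make_roster(roster_n(6, 2), majority_group = "red")
  ev <- events_tbl(list(c("r1", "r2"), c("r3", "r4"), c("b1", "b2"),
                        c("r1", "b1"), c("b2", "r5")))
  cc <- categorize_interactions(ev, ros)
  expect_equal(cc$count[cc$category == "majority_on_majority"], 2L)
  expect_equal(cc$count[cc$category == "minority_on_minority"], 1L)
  expect_equal(cc$count[cc$category == "mixed"], 2L)
  expect_equal(cc$m[1], 6L)
  expect_equal(cc$n[1], 2L)
  # cross-group events are mixed regardless of which color is the majority
  ros_b <- make_roster(roster_n(2, 6), majority_group = "blue")
  cc_b <- categorize_interactions(events_tbl(list(c("r1", "b1"))), ros_b)
  expect_equal(cc_b$count[cc_b$category == "mixed"], 1L)
  # unknown participant is a data error
  expect_error(categorize_interactions(events_tbl(list(c("x1", "r1"))), ros),
               "not in roster")
})

test_that("chance weights reproduce 30/44, 2/44, 12/44 at 6:2 and sum to 1", {
  w <- chance_weights(6, 2)
  expect_identical(unname(w["majority_on_majority"]), 30 / 44)
  expect_identical(unname(w["minority_on_minority"]), 2 / 44)
  expect_identical(unname(w["mixed"]), 12 / 44)
  for (mn in list(c(8, 0), c(7, 1), c(5, 3), c(4, 4), c(9, 5))) {
    expect_equal(sum(chance_weights(mn[1], mn[2])), 1)
  }
})

test_that("chance weights at 4:4 match exhaustive pair enumeration", {
  # independent oracle: enumerate ordered within-group pairs and unordered
  # cross pairs for m = n = 4 directly
  ids <- c(paste0("A", 1:4), paste0("B", 1:4))
  grp <- rep(c("A", "B"), each = 4)
  ordered_pairs <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
  ordered_pairs <- ordered_pairs[ordered_pairs$i != ordered_pairs$j, ]
  gi <- grp[match(ordered_pairs$i, ids)]
  gj <- grp[match(ordered_pairs$j, ids)]
  n_within_maj <- sum(gi == "A" & gj == "A")          # ordered: m(m-1)
  n_within_min <- sum(gi == "B" & gj == "B")
  n_cross_unordered <- sum(gi == "A" & gj == "B")     # unordered: m*n
  d <- n_within_maj + n_within_min + n_cross_unordered
  expect_equal(unname(chance_weights(4, 4)),
               c(n_within_maj, n_within_min, n_cross_unordered) / d)
  expect_equal(unname(chance_weights(4, 4)), c(12 / 40, 12 / 40, 16 / 40))
})

test_that("chance normalization maps chance-proportional counts to 1", {
  w <- chance_weights(6, 2)
  counts <- tibble::tibble(
    category = names(w), count = as.integer(round(440 * w)), m = 6L, n = 2L)
  out <- chance_normalize(counts)
  expect_equal(out$normalized, rep(1, 3))
  # and scales observed deviations correctly
  counts2 <- counts
  counts2$count <- c(300L, 40L, 100L)
  out2 <- chance_normalize(counts2)
  expect_equal(out2$normalized,
               (counts2$count / 440) / unname(w[counts2$category]))
  counts0 <- counts; counts0$count <- 0L
  expect_error(chance_normalize(counts0), "zero total")
})

test_that("group bias formula, range and symmetry", {
  expect_equal(group_bias(1, 1), 0.5)
  expect_equal(group_bias(0.5, 0.5), 0)
  expect_equal(group_bias(0.7, 0.6), 0.15)
  expect_equal(group_bias(0, 0), -0.5)
  expect_equal(group_bias(0.8, 0.3), group_bias(0.3, 0.8))
  expect_true(is.na(group_bias(NA, 0.5)))
})

test_that("summed bias adds complete series and rejects gaps", {
  expect_equal(summed_bias(rep(0.5, 10)), 5)
  expect_equal(summed_bias(rep(0, 4)), 0)
  expect_equal(summed_bias(c(0.5, 0.25, 0.125)), 0.875)
  expect_error(summed_bias(c(0.5, NA, 0.1)), "missing bins")
})

test_that("individuation gap and correlation behave as specified", {
  expect_equal(individuation_gap(0.9, 0.55), 0.35)
  expect_equal(individuation_gap(0.42, 0.42), 0)
  expect_equal(individuation_gap(0.5, 0.5), 0)
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(5)
  expect_lt(abs(pearson_r(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2))
})

test_that("full-environment bias statistic is zero at chance and extreme otherwise", {
  ros <- make_roster(roster_n(4, 4), majority_group = "red")
  w <- chance_weights(4, 4)
  # 40 events at exact chance proportions: 12 r-r, 12 b-b, 16 cross
  mk <- function(n_rr, n_bb, n_rb) {
    events_tbl(c(replicate(n_rr, c(sample(paste0("r", 1:4), 2)), simplify = FALSE),
                 replicate(n_bb, c(sample(paste0("b", 1:4), 2)), simplify = FALSE),
                 replicate(n_rb, c(sample(paste0("r", 1:4), 1),
                                   sample(paste0("b", 1:4), 1)), simplify = FALSE)))
  }
  set.seed(6)
  at_chance <- mk(12, 12, 16)
  expect_equal(full_env_bias(at_chance, ros), 0)
  all_within <- mk(20, 20, 0)
  expect_equal(full_env_bias(all_within, ros), 40 * (1 - 0.6))
  all_between <- mk(0, 0, 40)
  expect_equal(full_env_bias(all_between, ros), -40 * 0.6)
})
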