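test_that("recipe matching follows containment with deterministic ties", {
  rec <- tiny_recipes()
  # full title containment, order-free, extra tokens allowed
  expect_equal(match_recipe("chicken soup recipe", rec), "r001")
  expect_equal(match_recipe("soup chicken", rec), "r001")
  expect_equal(match_recipe("easy beef egg pie tonight", rec), "r002")
  # no food reference at all
  expect_true(is.na(match_recipe("weather tomorrow", rec)))
  # most-tokens-matched beats a contained shorter title
  expect_equal(match_recipe("chicken soup", rec), "r001")
  # bare one-token title still matches, smallest id on genuine ties
  expect_equal(match_recipe("chicken", rec), "r003")
  # fallback: "recipe" + ingredient name with no full title match
  expect_equal(match_recipe("recipe with salmon please", rec), "r004")
  expect_true(is.na(match_recipe("recipe ideas", rec)))
  # punctuation and case are normalized away
  expect_equal(match_recipe("CHICKEN, soup! Recipe?", rec), "r001")
})

test_that("synthetic queries are matched back to their generating recipe", {
  cfg <- small_config(seed = 61)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  ev <- sim$events[sim$truth$event_recipes$event_id, ]
  got <- match_recipes(ev$text, rec)
  expect_gt(mean(got == sim$truth$event_recipes$recipe_id), 0.95)
})

test_that("B12 query classification keys off normalized tokens", {
  out <- classify_b12_query(c(
    "b12 deficiency symptoms",
    "vitamin b-12 injections",
    "b 12 serum test",
    "b1 deficiency",
    "b12",
    "low b12 pills"
  ))
  expect_equal(out$is_b12, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$is_deficiency, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$is_supplement, c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$is_level, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # sub-flags imply the B12 flag
  expect_true(all(out$is_b12[out$is_deficiency | out$is_supplement | out$is_level]))
})

test_that("term matching is token-boundary and contiguous for phrases", {
  lex <- tibble::tibble(
    term = c("gabapentin", "tramadol", "back pain"),
    set = c("target", "target", "target")
  )
  expect_equal(match_terms("gabapentin dosage", lex), "gabapentin")
  expect_setequal(
    match_terms("tramadol vs gabapentin", lex),
    c("tramadol", "gabapentin")
  )
  expect_length(match_terms("gabapentinoid", lex), 0)
  expect_equal(match_terms("severe back pain relief", lex), "back pain")
  expect_length(match_terms("back severe pain", lex), 0)
})

test_that("aggregation counts every ingredient of each matched query", {
  rec <- tiny_recipes()
  lex <- tibble::tibble(term = "gabapentin", set = "target")
  events <- tibble::tibble(
    user_id = c("u1", "u1", "u2", "u3"),
    text = c(
      "beef egg pie recipe", "beef egg pie recipe",
      "weather tomorrow", "gabapentin dosage"
    ),
    region = c(0L, 0L, 1L, 1L)
  )
  prof <- aggregate_users(events, rec, lex)
  u1 <- prof[prof$user_id == "u1", ]
  expect_equal(u1$beef, 2)
  expect_equal(u1$egg, 2)
  expect_equal(sum(as.matrix(u1[food_reference()$food])), 4)
  # users with no recipe match are retained with zero counts
  expect_true("u2" %in% prof$user_id)
  expect_equal(sum(as.matrix(prof[prof$user_id == "u2", food_reference()$food])), 0)
  expect_true(prof$ask_gabapentin[prof$user_id == "u3"])
  expect_false(any(prof$asked_b12))
})

test_that("aggregation is order-independent and chunk-mergeable", {
  cfg <- small_config(seed = 71, n_users = 400)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  full <- aggregate_users(sim$events, rec, cfg$lexicon)
  perm <- withr::with_seed(1, sim$events[sample(nrow(sim$events)), ])
  expect_identical(full, aggregate_users(perm, rec, cfg$lexicon))
  half <- nrow(sim$events) %/% 2
  a <- aggregate_users(sim$events[1:half, ], rec, cfg$lexicon)
  b <- aggregate_users(sim$events[(half + 1):nrow(sim$events), ], rec, cfg$lexicon)
  merged <- combine_profiles(a, b)
  cols <- setdiff(names(full), "region") # modal region is not chunk-mergeable
  expect_equal(merged[cols], full[cols])
})

test_that("aggregated food counts equal the generator's emission tally", {
  cfg <- small_config(seed = 72)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  prof <- aggregate_users(sim$events, rec, cfg$lexicon)
  got <- colSums(as.matrix(prof[food_reference()$food]))
  want <- colSums(as.matrix(sim$truth$food_counts[food_reference()$food]))
  # ties between identically-titled recipes can swap ingredient sets for a
  # tiny fraction of events; totals must agree almost exactly
  expect_lt(sum(abs(got - want)) / sum(want), 0.02)
})

test_that("empty user ids are skipped and modal region breaks ties low", {
  rec <- tiny_recipes()
  lex <- tibble::tibble(term = "gabapentin", set = "target")
  events <- tibble::tibble(
    user_id = c("", "u1", "u1", "u1", "u1"),
    text = c("x", "chicken soup recipe", "a", "b", "c"),
    region = c(0L, 3L, 1L, 3L, 1L)
  )
  expect_message(prof <- aggregate_users(events, rec, lex), "1 event")
  expect_equal(nrow(prof), 1)
  expect_equal(prof$region, 1L)
})

test_that("the asker filter applies an inclusive threshold", {
  lex <- tibble::tibble(
    term = c("gabapentin", "tramadol", "eczema"),
    set = c("target", "target", "control")
  )
  counts <- matrix(0L, 10, 12)
  prof <- toy_profiles(
    counts,
    ask_gabapentin = rep(c(TRUE, FALSE), c(5, 5)),
    ask_tramadol = rep(c(TRUE, FALSE), c(4, 6)),
    ask_eczema = rep(c(TRUE, FALSE), c(7, 3))
  )
  kept <- filter_terms(prof, lex, min_askers = 5)
  expect_equal(kept$term, c("eczema", "gabapentin"))
  expect_equal(kept$n_askers, c(7L, 5L))
  all_kept <- filter_terms(prof, lex, min_askers = 1)
  expect_equal(nrow(all_kept), 3)
  expect_error(filter_terms(prof, lex, min_askers = 0), "at least 1")
})

test_that("deficiency-asker share converges to the awareness rate", {
  cfg <- small_config(seed = 81, n_users = 20000)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  prof <- aggregate_users(sim$events, rec, cfg$lexicon)
  p <- binom.test(sum(prof$asked_deficiency), nrow(prof), p = 0.01)$p.value
  expect_gt(p, 0.001)
})

test_that("log round-trips through the tab-separated interchange format", {
  cfg <- small_config(seed = 91, n_users = 50)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_search_log(sim$events, tmp)
  back <- read_search_log(tmp)
  expect_equal(
    back[c("user_id", "text", "region")],
    sim$events[c("user_id", "text", "region")]
  )
  rtmp <- withr::local_tempfile(fileext = ".csv")
  write_recipes(rec, rtmp)
  rback <- read_recipes(rtmp)
  expect_equal(rback$ingredients, rec$ingredients, ignore_attr = TRUE)
})
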