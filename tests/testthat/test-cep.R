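rules <- default_rules()
rule_of <- function(out) rules[rules$output == out, ]

test_that("repeat (C1) rules need an unbroken run of identical postures", {
  dig2 <- posture_events("d", "body", c("Dig", "Dig"), c(0, 1))
  ev <- match_c1(dig2, rule_of("Digging"))
  expect_equal(ev$behavior, "Digging")
  expect_equal(c(ev$ts, ev$te), c(0, 2))
  mixed <- posture_events("d", "body", c("Dig", "Walk"), c(0, 1))
  expect_equal(nrow(match_c1(mixed, rule_of("Digging"))), 0)
  bark <- posture_events("d", "head", c("Bark", "Bark"), c(0, 1))
  expect_equal(match_c1(bark, rule_of("Barking"))$behavior, "Barking")
  # a head event does not interrupt a body run
  with_head <- dplyr::arrange(dplyr::bind_rows(
    posture_events("d", "body", c("Lie", "Lie"), c(0, 1)),
    posture_events("d", "head", "Up", 0.5)), t)
  expect_equal(match_c1(with_head, rule_of("Lying"))$behavior, "Lying")
})

test_that("follow (C2) rule needs body Walk/Stand strictly before head Down", {
  walk_down <- dplyr::bind_rows(posture_events("d", "body", "Walk", 0),
                                posture_events("d", "head", "Down", 1))
  ev <- match_c2(walk_down, rule_of("Sniffing"))
  expect_equal(c(ev$ts, ev$te), c(0, 2))
  stand_down <- dplyr::bind_rows(posture_events("d", "body", "Stand", 0),
                                 posture_events("d", "head", "Down", 1))
  expect_equal(match_c2(stand_down, rule_of("Sniffing"))$behavior, "Sniffing")
  reversed <- dplyr::bind_rows(posture_events("d", "head", "Down", 0),
                               posture_events("d", "body", "Walk", 1))
  expect_equal(nrow(match_c2(reversed, rule_of("Sniffing"))), 0)
  simultaneous <- dplyr::bind_rows(posture_events("d", "body", "Walk", 1),
                                   posture_events("d", "head", "Down", 1))
  expect_equal(nrow(match_c2(simultaneous, rule_of("Sniffing"))), 0)
})

test_that("disjunctive operands behave as set membership (de Morgan)", {
  r <- rule_of("Sniffing")
  r_walk <- r
  r_walk$operand1 <- list("Walk")
  r_stand <- r
  r_stand$operand1 <- list("Stand")
  set.seed(11)
  for (i in 1:25) {
    view <- random_l1_stream(2)
    fired <- nrow(match_c2(view, r)) > 0
    fired_walk <- nrow(match_c2(view, r_walk)) > 0
    fired_stand <- nrow(match_c2(view, r_stand)) > 0
    # A-or-B fires iff A fires or B fires; not(A or B) == not A and not B
    expect_equal(fired, fired_walk || fired_stand)
    expect_equal(!fired, !fired_walk && !fired_stand)
  }
})

test_that("scan_atomic consumes postures so runs are not double-counted", {
  walk4 <- posture_events("d", "body", rep("Walk", 4), 0:3)
  l2 <- scan_atomic(walk4, rules)
  expect_equal(l2$ts, c(0, 2))
  expect_equal(l2$te, c(2, 4))
  walk3 <- posture_events("d", "body", rep("Walk", 3), 0:2)
  expect_equal(nrow(scan_atomic(walk3, rules)), 1)
  expect_equal(nrow(scan_atomic(event_channel("L1"), rules)), 0)
  alternating <- posture_events("d", "body",
                                rep(c("Walk", "Sit"), 5), 0:9)
  expect_equal(nrow(scan_atomic(alternating, rules)), 0)
  unsorted <- posture_events("d", "body", c("Walk", "Walk"), c(1, 0))
  expect_error(scan_atomic(unsorted, rules), "sorted")
})

test_that("every emitted event satisfies ts < te and lies in its window", {
  set.seed(21)
  for (i in 1:10) {
    l1 <- random_l1_stream(20)
    l2 <- scan_atomic(l1, rules)
    if (nrow(l2)) {
      expect_true(all(l2$ts < l2$te))
      expect_true(all(l2$te - l2$ts == 2))
      expect_true(all(l2$ts >= 0 & l2$te <= max(l1$t) + 2))
    }
  }
})

test_that("coverage_fraction unions intervals and clips to the window", {
  expect_equal(coverage_fraction(atomic_events(character(), character(),
                                               numeric(), numeric()),
                                 "Walking", t_start = 0)$f, 0)
  full <- atomic_events("d", rep("Walking", 8), seq(0, 14, 2),
                        seq(2, 16, 2))
  expect_equal(coverage_fraction(full, "Walking", t_start = 0)$f, 1)
  disjoint <- atomic_events("d", c("Walking", "Sniffing"), c(0, 5),
                            c(3, 6.5))
  expect_equal(coverage_fraction(disjoint, c("Walking", "Sniffing"),
                                 t_start = 0)$f, 0.3)
  # overlap counted once
  overlapping <- atomic_events("d", c("Walking", "Walking"), c(0, 1), c(2, 3))
  expect_equal(coverage_fraction(overlapping, "Walking", t_start = 0)$f,
               3 / 15)
  # non-member classes ignored
  expect_equal(coverage_fraction(overlapping, "Barking", t_start = 0)$f, 0)
})

test_that("coverage_fraction is monotone and invariant to interval splits", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    ts <- sort(stats::runif(n, 0, 13))
    ev <- atomic_events("d", sample(c("Walking", "Sniffing"), n, TRUE),
                        ts, ts + stats::runif(n, 0.5, 2))
    f0 <- coverage_fraction(ev, c("Walking", "Sniffing"), t_start = 0)$f
    # adding an event never decreases coverage
    more <- dplyr::bind_rows(ev, atomic_events("d", "Walking", 4, 5.5))
    f1 <- coverage_fraction(more, c("Walking", "Sniffing"), t_start = 0)$f
    expect_gte(f1 + 1e-12, f0)
    # splitting one interval into abutting halves changes nothing
    split <- dplyr::bind_rows(
      ev[-1, ],
      atomic_events("d", ev$behavior[1], c(ev$ts[1], mean(c(ev$ts[1], ev$te[1]))),
                    c(mean(c(ev$ts[1], ev$te[1])), ev$te[1])))
    f2 <- coverage_fraction(split, c("Walking", "Sniffing"), t_start = 0)$f
    expect_equal(f2, f0, tolerance = 1e-12)
  }
})

test_that("detect_complex diagnoses every behavior on tumbling windows", {
  # no events at all in a known span: all three behaviors Normal
  quiet <- scan_atomic(posture_events("d", "body", rep("Sit", 15), 0:14),
                       rules)
  l3 <- detect_complex(quiet, rules, t_end = 15)
  expect_equal(nrow(l3), 3)
  expect_true(all(l3$d == "Normal"))
  expect_setequal(l3$behavior, complex_classes())
  # a window fully covered by Walking flags Exploratory
  walking <- scan_atomic(posture_events("d", "body", rep("Walk", 15), 0:14),
                         rules)
  l3w <- detect_complex(walking, rules, t_end = 15)
  expect_equal(l3w$d[l3w$behavior == "Exploratory"], "Abnormal")
  expect_equal(l3w$d[l3w$behavior == "Destructive"], "Normal")
  # two windows -> six events
  l3x <- detect_complex(walking, rules, t_end = 30)
  expect_equal(nrow(l3x), 6)
})

test_that("run_hierarchy composes the levels deterministically", {
  empty <- run_hierarchy(event_channel("L1"))
  expect_equal(nrow(empty$l2), 0)
  expect_equal(nrow(empty$l3), 0)
  # an hour of Lying carries no separation-anxiety signal
  hour <- posture_events("d", "body", rep("Lie", 3600), 0:3599)
  h <- run_hierarchy(hour)
  expect_true(all(h$l2$behavior == "Lying"))
  expect_equal(sum(h$l3$d == "Abnormal"), 0)
  expect_equal(nrow(h$l3), 3 * 240)
  # determinism
  set.seed(41)
  l1 <- random_l1_stream(30)
  h1 <- run_hierarchy(l1)
  h2 <- run_hierarchy(l1)
  expect_identical(h1, h2)
})

test_that("rule sets round-trip through YAML and reproduce the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(as.data.frame(back), as.data.frame(rules))
  # every atomic class is produced by some rule; complex operands are produced
  produced <- back$output[back$kind != "aggregate_a"]
  expect_setequal(produced, atomic_classes())
  agg <- back[back$kind == "aggregate_a", ]
  expect_true(all(unlist(agg$operand1) %in% produced))
})
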