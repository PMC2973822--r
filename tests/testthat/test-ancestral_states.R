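test_that("parsimony score on canonical small trees", {
  # uniform tips: no change
  same <- tip_state_tree("((A,B),(C,D));",
                         c(A = "E", B = "E", C = "E", D = "E"))
  expect_equal(parsimony_changes(same)$min_changes, 0L)

  # one V clade under an E root: a single E->V change
  one <- tip_state_tree("((A,B),(C,D));",
                        c(A = "V", B = "V", C = "E", D = "E"))
  cc <- parsimony_changes(one, root_state = "E")
  expect_equal(cc$min_changes, 1L)
  ev <- cc$per_transition[cc$per_transition$from == "E" &
                          cc$per_transition$to == "V", ]
  expect_equal(c(ev$min, ev$max), c(1L, 1L))

  # two disjoint V clades: two E->V changes
  two <- tip_state_tree("(((A,B),(C,D)),((E,F),(G,H)));",
                        c(A = "V", B = "V", C = "E", D = "E",
                          E = "V", F = "V", G = "E", H = "E"))
  cc2 <- parsimony_changes(two, root_state = "E")
  expect_equal(cc2$min_changes, 2L)
  ev2 <- cc2$per_transition[cc2$per_transition$from == "E" &
                            cc2$per_transition$to == "V", ]
  expect_equal(c(ev2$min, ev2$max), c(2L, 2L))

  expect_error(tip_state_tree("((A,B),(C,D));", c(A = "V", B = "V", C = "E")),
               "unstated tip")
})

test_that("score and transition ranges equal the exhaustive oracle", {
  for (seed in 1:20) {
    x <- random_tip_state_tree(ntips = sample(4:8, 1), n_states = 2,
                               seed = seed)
    cc <- parsimony_changes(x)
    oracle <- oracle_parsimony(x$tree, x$states,
                               alphabet = sort(unique(x$states)))
    expect_equal(cc$min_changes, oracle$score)
    for (i in seq_len(nrow(cc$per_transition))) {
      fr <- cc$per_transition$from[i]; to <- cc$per_transition$to[i]
      expect_equal(cc$per_transition$min[i], as.integer(oracle$trans_min[fr, to]),
                   info = sprintf("seed %d %s->%s min", seed, fr, to))
      expect_equal(cc$per_transition$max[i], as.integer(oracle$trans_max[fr, to]),
                   info = sprintf("seed %d %s->%s max", seed, fr, to))
    }
    # the returned reconstruction attains the score
    e <- x$tree$edge
    lab <- cc$reconstruction
    expect_equal(sum(lab[e[, 1]] != lab[e[, 2]]), cc$min_changes)
  }
  # three-state alphabet too
  x3 <- random_tip_state_tree(ntips = 6, n_states = 3, seed = 33)
  oc3 <- oracle_parsimony(x3$tree, x3$states)
  expect_equal(parsimony_changes(x3)$min_changes, oc3$score)
})

test_that("score is invariant under re-rooting when no root state is imposed", {
  for (seed in c(3, 4)) {
    x <- random_tip_state_tree(ntips = 8, n_states = 2, seed = seed)
    sc <- parsimony_changes(x)$min_changes
    for (out in x$tree$tip.label[c(2, 5)]) {
      rerooted <- ape::root(x$tree, outgroup = out, resolve.root = TRUE)
      expect_equal(parsimony_changes(tip_state_tree(rerooted, x$states))$min_changes,
                   sc)
    }
  }
})

test_that("adding a tip identical to its sister never increases the score", {
  for (seed in 11:14) {
    x <- random_tip_state_tree(ntips = 6, n_states = 2, seed = seed)
    sc <- parsimony_changes(x)$min_changes
    # duplicate tip t1 as its own sister
    nwk <- ape::write.tree(x$tree)
    nwk2 <- sub("t1:", "(t1:0,t1dup:0):", nwk, fixed = TRUE)
    st2 <- c(x$states, t1dup = unname(x$states["t1"]))
    sc2 <- parsimony_changes(tip_state_tree(nwk2, st2))$min_changes
    expect_lte(sc2, sc)
    expect_equal(sc2, sc)  # unit costs: an identical sister adds nothing
  }
})

test_that("polytomies are handled natively", {
  x <- tip_state_tree("(A,B,C,D,E);",
                      c(A = "V", B = "V", C = "E", D = "E", E = "E"))
  expect_equal(parsimony_changes(x, root_state = "E")$min_changes, 2L)
  oracle <- oracle_parsimony(x$tree, x$states)
  expect_equal(parsimony_changes(x)$min_changes, oracle$score)
})

test_that("incompatible root states are reported, not forced", {
  x <- tip_state_tree("((A,B),(C,D));",
                      c(A = "V", B = "V", C = "V", D = "V"))
  expect_warning(cc <- parsimony_changes(x, root_state = "E"),
                 "incompatible")
  expect_false(cc$root_state_ok)
  expect_equal(cc$min_changes, 0L)
})

test_that("gain/loss ranges behave on directed cases", {
  one <- tip_state_tree("((A,B),(C,D));",
                        c(A = "V", B = "V", C = "E", D = "E"))
  rv <- count_reversions(one, ancestral = "E", derived = "V",
                         root_state = "E")
  expect_equal(unname(rv$gains), c(1L, 1L))
  expect_equal(unname(rv$losses), c(0L, 0L))

  # alternating caterpillar: every MPR's gains + losses equal the score
  cat6 <- tip_state_tree("(A,(B,(C,(D,(E,F)))));",
                         c(A = "V", B = "E", C = "V", D = "E", E = "V",
                           F = "E"))
  cc <- parsimony_changes(cat6)
  oracle <- oracle_parsimony(cat6$tree, cat6$states)
  expect_equal(cc$min_changes, oracle$score)
  rv2 <- count_reversions(cat6, "E", "V")
  # with a binary alphabet all changes are gains or losses
  expect_equal(unname(rv2$gains["min"] + rv2$losses["max"]), cc$min_changes)
  expect_equal(unname(rv2$gains["max"] + rv2$losses["min"]), cc$min_changes)

  # ancestral state absent from tips: losses exceed gains only under an
  # ancestral root (checked against the enumeration oracle)
  allv <- tip_state_tree("((A,B),(C,D));",
                         c(A = "V", B = "V", C = "V", D = "V"))
  rv3 <- count_reversions(allv, "E", "V")
  expect_equal(unname(rv3$gains), c(0L, 0L))
  expect_equal(unname(rv3$losses), c(0L, 0L))
})

test_that("simulated substitution events on disjoint edges are recovered", {
  # one E->V event above a 2-tip clade of a 4-tip tree
  st <- simulate_tip_states("((A,B),(C,D));",
                            list(list(edge = c("A", "B"), from = "E",
                                      to = "V")), root_state = "E")
  expect_equal(parsimony_changes(st, root_state = "E")$min_changes, 1L)

  # k events on disjoint terminal edges of a balanced tree, k = 1..8
  tips <- paste0("t", 1:16)
  nwk <- paste0("((((t1,t2),(t3,t4)),((t5,t6),(t7,t8))),",
                "(((t9,t10),(t11,t12)),((t13,t14),(t15,t16))));")
  for (k in c(1, 4, 8)) {
    ev <- lapply(tips[seq_len(k) * 2], function(t)
      list(edge = t, from = "E", to = "V"))
    st <- simulate_tip_states(nwk, ev, root_state = "E")
    expect_equal(parsimony_changes(st, root_state = "E")$min_changes, k)
  }
})
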