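test_that("majority-rule transfer follows the strict more-than-half rule", {
  om <- as_ortholog_map(data.frame(
    species = c("dog", "dog", rep("cat", 4)),
    protein_id = c("D1", "D2", "c1", "c2", "c3", "c4"),
    group_id = c("G1", "G2", "G1", "G1", "G2", "G2")))
  mk_net <- function(a, b) {
    scored_network(data.frame(protein_a = a, protein_b = b,
                              score = rep(0.9, length(a))))
  }
  # 1x1 groups with the single pair interacting
  om1 <- as_ortholog_map(data.frame(species = c("dog", "dog", "cat", "cat"),
                                    protein_id = c("D1", "D2", "c1", "c2"),
                                    group_id = c("G1", "G2", "G1", "G2")))
  expect_equal(transfer_interaction("D1", "D2", "cat", om1,
                                    mk_net("c1", "c2")), "present")
  # 2x2: 3 of 4 -> present; exactly 2 of 4 -> absent
  expect_equal(transfer_interaction("D1", "D2", "cat", om,
                                    mk_net(c("c1", "c1", "c2"),
                                           c("c3", "c4", "c3"))), "present")
  expect_equal(transfer_interaction("D1", "D2", "cat", om,
                                    mk_net(c("c1", "c2"), c("c3", "c4"))),
               "absent")
  # sub-threshold edges do not count
  low <- scored_network(data.frame(protein_a = c("c1", "c1", "c2"),
                                   protein_b = c("c3", "c4", "c3"),
                                   score = c(0.9, 0.69, 0.69)))
  expect_equal(transfer_interaction("D1", "D2", "cat", om, low), "absent")
  # empty group in the species -> unknown; unmapped focal protein -> unknown
  expect_equal(transfer_interaction("D1", "D2", "horse", om,
                                    mk_net("c1", "c3")), "unknown")
  expect_equal(suppressMessages(
    transfer_interaction("D1", "D9", "cat", om, mk_net("c1", "c3"))),
    "unknown")
  # symmetric in the two proteins
  net <- mk_net(c("c1", "c1", "c2"), c("c3", "c4", "c3"))
  expect_equal(transfer_interaction("D1", "D2", "cat", om, net),
               transfer_interaction("D2", "D1", "cat", om, net))
})

test_that("majority-rule transfer matches exhaustive enumeration up to 3x3 groups", {
  for (m in 1:3) {
    for (k in 1:3) {
      ga <- sprintf("a%d", seq_len(m))
      gb <- sprintf("b%d", seq_len(k))
      om <- as_ortholog_map(data.frame(
        species = c("dog", "dog", rep("cat", m + k)),
        protein_id = c("D1", "D2", ga, gb),
        group_id = c("G1", "G2", rep("G1", m), rep("G2", k))))
      cross <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
      n_cross <- nrow(cross)
      for (n_int in 0:n_cross) {
        idx <- seq_len(n_int)
        net <- scored_network(data.frame(
          protein_a = c(cross$a[idx], "zzz1"),
          protein_b = c(cross$b[idx], "zzz2"),
          score = 0.9))
        got <- transfer_interaction("D1", "D2", "cat", om, net)
        want <- if (n_int / n_cross > 0.5) "present" else "absent"
        expect_equal(got, want)
      }
    }
  }
})

test_that("parsimony reconstruction handles the canonical tree cases", {
  tree <- species_tree()
  # constant character: no changes anywhere
  all1 <- setNames(rep(1, 6), tree$tip.label)
  f <- fitch_reconstruct(tree, all1)
  expect_equal(f$score, 0)
  expect_true(all(f$node_states == 1))
  # single dog presence: one gain on the dog terminal branch
  st <- c(dog = 1, cat = 0, horse = 0, pig = 0, cow = 0, mouse = 0)
  f <- fitch_reconstruct(tree, st)
  expect_equal(f$score, 1)
  expect_equal(unname(f$node_states[setdiff(names(f$node_states), "dog")]),
               rep(0, 10))
  # dog and cat present: gain on the branch into their ancestor
  st2 <- c(dog = 1, cat = 1, horse = 0, pig = 0, cow = 0, mouse = 0)
  f2 <- fitch_reconstruct(tree, st2)
  expect_equal(f2$score, 1)
  dogcat <- snpnetevo:::tree_node_names(tree)[ape::getMRCA(tree, c("dog", "cat"))]
  expect_equal(unname(f2$node_states[dogcat]), 1)
  expect_equal(unname(f2$node_states["A2"]), 0)  # five-species ancestor
  # unknown tips are unconstrained; all-unknown is an error
  expect_equal(fitch_reconstruct(tree, c(dog = 1, cat = NA, horse = NA,
                                         pig = NA, cow = NA, mouse = NA))$score, 0)
  expect_error(fitch_reconstruct(tree, setNames(rep(NA_real_, 6),
                                                tree$tip.label)),
               "all tip states unknown")
  # accepted state strings work too
  f3 <- fitch_reconstruct(tree, c(dog = "present", cat = "absent",
                                  horse = "absent", pig = "absent",
                                  cow = "absent", mouse = "unknown"))
  expect_equal(f3$score, 1)
})

test_that("parsimony score equals brute-force enumeration on random trees", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:25) {
    ntips <- sample(4:8, 1)
    tree <- ape::rtree(ntips)
    for (ch in 1:8) {
      st <- sample(c(0, 1, NA), ntips, replace = TRUE, prob = c(.4, .4, .2))
      if (all(is.na(st))) st[1] <- 1
      names(st) <- tree$tip.label
      for (resolve in c("deltran", "acctran")) {
        m <- matrix(st, nrow = 1, dimnames = list("x", tree$tip.label))
        rec <- fitch_reconstruct_many(tree, m, outgroup = tree$tip.label[1],
                                      resolve = resolve)
        expect_equal(unname(rec$score), brute_force_parsimony(tree, st))
        # resolved states realize exactly the parsimony score
        realized <- sum(rec$node_states[, rec$branches$parent_idx] !=
                          rec$node_states[, rec$branches$child_idx])
        expect_equal(realized, unname(rec$score))
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("parsimony scores agree with an independent phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tree <- ape::rtree(8)
  states <- matrix(sample(0:1, 8 * 50, replace = TRUE), ncol = 8,
                   dimnames = list(NULL, tree$tip.label))
  rec <- fitch_reconstruct_many(tree, states, outgroup = tree$tip.label[1])
  dat <- phangorn::phyDat(t(states) + 1, type = "USER", levels = 1:2)
  per_pattern <- phangorn::fitch(tree, dat, site = "site")
  expect_equal(unname(rec$score),
               unname(per_pattern[attr(dat, "index")]))
})

test_that("branch accounting conserves changes and reports denominators", {
  tree <- species_tree()
  # single pair gained on the dog branch
  st <- matrix(c(1, 0, 0, 0, 0, 0), nrow = 1,
               dimnames = list("p1", tree$tip.label))
  rec <- fitch_reconstruct_many(tree, st)
  bs <- branch_change_summary(rec)
  dog <- bs[bs$branch_id == "dog", ]
  expect_equal(dog$gains, 1L)
  expect_equal(dog$gain_fraction, 1.0)
  expect_equal(dog$n_without_at_parent, 1L)
  expect_true(is.na(dog$loss_fraction))  # no pair present at the parent
  expect_equal(sum(bs$gains) + sum(bs$losses), sum(rec$score))
  # conservation identity over many random profiles
  set.seed(13)
  states <- matrix(sample(c(0, 1, NA), 6 * 400, replace = TRUE,
                          prob = c(.4, .4, .2)), ncol = 6,
                   dimnames = list(sprintf("p%03d", 1:400), tree$tip.label))
  states[rowSums(!is.na(states)) == 0, 1] <- 0
  rec <- fitch_reconstruct_many(tree, states)
  bs <- branch_change_summary(rec)
  expect_equal(sum(bs$gains) + sum(bs$losses), sum(rec$score))
})

test_that("a loss-free simulation contains no true losses and reconstructs none when gains are confined to one branch", {
  tree <- species_tree()
  # the true history contains no 1 -> 0 transition anywhere
  h <- simulate_interaction_history(tree, n_pairs = 300, gain_rate = 0.1,
                                    loss_rate = 0, root_present_prob = 0,
                                    rng_seed = 5)
  st <- h$truth$states
  br <- snpnetevo:::tree_branches(tree)
  true_losses <- sum(vapply(seq_len(nrow(br)), function(k) {
    sum(st[, br$parent_idx[k]] == 1 & st[, br$child_idx[k]] == 0)
  }, numeric(1)))
  expect_equal(true_losses, 0)
  # when gains cannot converge (single gaining branch), the reconstruction
  # is loss-free too; convergent independent gains can legitimately be
  # reconstructed as an ancestral gain plus losses, so that case is excluded
  h1 <- simulate_interaction_history(tree, n_pairs = 300, gain_rate = 1e-9,
                                     loss_rate = 0, root_present_prob = 0,
                                     excess_factor = 1e9, rng_seed = 6)
  rec <- fitch_reconstruct_many(tree, h1$truth$states[, tree$tip.label])
  bs <- branch_change_summary(rec)
  expect_equal(sum(bs$losses), 0L)
})

test_that("randomization test is deterministic, floored and monotone", {
  tree <- species_tree()
  h <- simulate_interaction_history(tree, n_pairs = 400, excess_factor = 8,
                                    rng_seed = 2)
  prof <- suppressMessages(build_interaction_profiles(
    h$pairs, h$ortholog_map, h$networks, species = tree$tip.label))
  rec <- fitch_reconstruct_many(tree, snpnetevo:::profiles_to_states(prof))
  rt1 <- randomization_test(rec, h$truth$planted_pairs, n = 500, rng_seed = 9)
  rt2 <- randomization_test(rec, h$truth$planted_pairs, n = 500, rng_seed = 9)
  expect_identical(rt1, rt2)
  expect_true(all(rt1$p_value >= 1 / 501, na.rm = TRUE))
  expect_true(all(rt1$p_value <= 1, na.rm = TRUE))
  # strongly enriched dog branch hits the add-one floor
  expect_equal(rt1$p_value[rt1$branch_id == "dog"], 1 / 501)
  expect_error(randomization_test(rec, "nonexistent|pair"), "not in universe")
})

test_that("profiles reproduce the simulated tip states wherever they are known", {
  tree <- species_tree()
  h <- simulate_interaction_history(tree, n_pairs = 250, rng_seed = 31)
  prof <- suppressMessages(build_interaction_profiles(
    h$pairs, h$ortholog_map, h$networks, species = tree$tip.label))
  true_tips <- h$truth$states[, tree$tip.label]
  known <- prof != "unknown"
  expect_true(all((prof == "present")[known] == (true_tips == 1)[known]))
  # the focal species is never unknown
  expect_true(all(prof[, "dog"] != "unknown"))
})
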