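three_taxon <- function(a, b, c) {
  list(tree = read_newick("((A,B),C);"),
       col = tibble::tibble(taxon = c("A", "B", "C"), state = c(a, b, c)))
}

test_that("worked micro-examples match the exhaustive oracle", {
  # ((A,B),C) with A=0, B=1, C=0: one change, root unambiguously absent
  x <- three_taxon("absent", "present", "absent")
  m <- mpr_sets(x$tree, x$col)
  b <- brute_force_mpr(x$tree, x$col)
  expect_same_mpr(m, b)
  expect_equal(m$tree_length, 1L)
  root <- m$states[m$states$node == 4L, ]
  expect_true(root$absent); expect_false(root$present)
  expect_equal(root$call, "A")
  inner <- m$states[m$states$node == 5L, ]
  expect_equal(inner$call, "A")

  # ((A,B),C) with A=0, B=?, C=1: one change, root equivocal
  y <- three_taxon("absent", "uncertain", "present")
  m2 <- mpr_sets(y$tree, y$col)
  expect_same_mpr(m2, brute_force_mpr(y$tree, y$col))
  expect_equal(m2$tree_length, 1L)
  root2 <- m2$states[m2$states$node == 4L, ]
  expect_equal(root2$call, "U")

  # downpass vectors for the same cases
  dp <- parsimony_downpass(x$tree, x$col)
  expect_equal(unname(dp[4, ]), c(1L, 2L))
  dp2 <- parsimony_downpass(y$tree,
                            tibble::tibble(taxon = c("A", "B", "C"),
                                           state = c("absent", "uncertain", "present")))
  expect_equal(unname(dp2[4, ]), c(1L, 1L))
})

test_that("degenerate columns behave", {
  tr <- read_newick("((A,B),C);")
  mono <- tibble::tibble(taxon = c("A", "B", "C"), state = "present")
  m <- mpr_sets(tr, mono)
  expect_equal(m$tree_length, 0L)
  expect_true(all(m$states$call == "P"))

  blank <- tibble::tibble(taxon = c("A", "B", "C"), state = "uncertain")
  m2 <- mpr_sets(tr, blank)
  expect_equal(m2$tree_length, 0L)
  expect_true(all(m2$states$call == "U"))

  single <- read_newick("(A);")
  expect_equal(tree_length(single, tibble::tibble(taxon = "A", state = "present")), 0L)

  expect_error(tree_length(tr, tibble::tibble(taxon = c("A", "B"), state = "absent")),
               "no character entry.*C")
})

test_that("star trees follow the min(k, n-k) closed form", {
  for (n in c(4, 7, 10)) {
    for (k in 0:n) {
      tr <- read_newick(paste0("(", paste0("t", 1:n, collapse = ","), ");"))
      col <- tibble::tibble(taxon = paste0("t", 1:n),
                            state = rep(c("present", "absent"), c(k, n - k)))
      expect_equal(tree_length(tr, col), min(k, n - k))
    }
  }
  # two-cherry derived example
  tr <- read_newick("((A,B),(C,D));")
  col <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                        state = c("absent", "present", "absent", "present"))
  expect_equal(tree_length(tr, col), 2L)
  expect_equal(brute_force_mpr(tr, col)$tree_length, 2L)
})

test_that("dynamic programme agrees with the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:150) {
    tr <- rand_tree(sample(4:10, 1), max_split = 4L)
    col <- rand_column(tr, p_uncertain = 0.25)
    expect_same_mpr(mpr_sets(tr, col), brute_force_mpr(tr, col))
  }
})

test_that("tree length is invariant to rerooting", {
  set.seed(21)
  for (rep in 1:20) {
    tr <- rand_tree(sample(5:10, 1), max_split = 2L)
    col <- rand_column(tr)
    len <- tree_length(tr, col)
    for (og in sample(tr$tip.label, 3)) {
      rt <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
      expect_equal(tree_length(rt, col), len)
    }
  }
})

test_that("an uncertain leaf is neutral: deleting it changes nothing else", {
  set.seed(5)
  for (rep in 1:20) {
    tr <- rand_tree(sample(5:9, 1), max_split = 3L)
    col <- rand_column(tr, p_uncertain = 0.3)
    victim <- sample(tr$tip.label, 1)
    col$state[col$taxon == victim] <- "uncertain"
    full <- mpr_sets(tr, col)
    pruned_tree <- prune_clade(tr, victim)
    pruned <- mpr_sets(pruned_tree, col[col$taxon != victim, ])
    expect_identical(pruned$tree_length, full$tree_length)
    # match surviving nodes by descendant leaf set; the victim's tip and its
    # stem node (suppressed by the prune) do not survive and are excluded
    key <- function(m, tree) {
      vapply(m$states$node, function(v) {
        paste(sort(setdiff(clade_tips(tree, v), victim)), collapse = "|")
      }, character(1))
    }
    victim_id <- match(victim, tr$tip.label)
    stem_id <- tr$edge[tr$edge[, 2] == victim_id, 1]
    kf <- key(full, tr)
    kf[full$states$node %in% c(victim_id, stem_id)] <- ""
    kp <- key(pruned, pruned_tree)
    shared <- intersect(kf[nzchar(kf)], kp)
    for (k in shared) {
      a <- full$states[match(k, kf), c("absent", "present")]
      b <- pruned$states[match(k, kp), c("absent", "present")]
      expect_identical(unname(as.logical(a)), unname(as.logical(b)))
    }
  }
})

test_that("adding a leaf never decreases tree length", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- rand_tree(sample(4:8, 1))
    col <- rand_column(tr)
    len <- tree_length(tr, col)
    target <- sample(tr$tip.label, 1)
    g <- graft_sister(tr, "extra", target)
    for (st in c("absent", "present", "uncertain")) {
      col2 <- rbind(col, tibble::tibble(taxon = "extra", state = st))
      expect_gte(tree_length(g$tree, col2), len)
    }
  }
})

test_that("Sankoff length equals Fitch intersection failures on binary trees", {
  set.seed(3)
  for (rep in 1:30) {
    tr <- rand_tree(sample(4:12, 1), max_split = 2L)
    col <- rand_column(tr, p_uncertain = 0)
    expect_equal(tree_length(tr, col), fitch_failures(tr, col))
  }
})

test_that("length agrees with phangorn's parsimony on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:15) {
    tr <- rand_tree(sample(4:12, 1), max_split = 2L)
    col <- rand_column(tr, p_uncertain = 0.2)
    dat <- lapply(stats::setNames(col$state, col$taxon), function(s) {
      switch(s, absent = "0", present = "1", uncertain = "?")
    })
    pd <- phangorn::phyDat(matrix(unlist(dat), ncol = 1,
                                  dimnames = list(names(dat), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(tree_length(tr, col),
                 as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("brute force refuses oversized trees and serializes cleanly", {
  tr <- rand_tree(40, max_split = 2L)
  expect_error(brute_force_mpr(tr, rand_column(tr)), "16")

  x <- three_taxon("absent", "present", "absent")
  js <- jsonlite::fromJSON(mpr_json(mpr_sets(x$tree, x$col)))
  expect_equal(js$tree_length, 1L)
  expect_equal(js$node_sets$A, "absent")
})
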