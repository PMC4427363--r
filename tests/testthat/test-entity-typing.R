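test_that("entity mentions are typed like the UMLS example sentence", {
  u <- prep_units(list(
    drug = "Avelox",
    side_effects = "Over the course of three nights, Avelox caused heart palpitations, confusion, and lasting muscle weakness."
  ))
  m <- tag_entities(u, example_lexicon(), affected_groups = c("DISO", "ANAT"))
  got <- m[, c("lemma", "sem_type", "sem_group")]
  expect_true(all(c("avelox", "confusion", "muscle weakness") %in% got$lemma))
  expect_equal(got$sem_type[got$lemma == "avelox"], "phsu")
  expect_equal(got$sem_group[got$lemma == "avelox"], "CHEM")
  expect_equal(got$sem_type[got$lemma == "muscle weakness"], "sosy")
  expect_equal(got$sem_group[got$lemma == "confusion"], "DISO")
  expect_equal(got$sem_type[got$lemma == "course"], "tmco")
  # "heart palpitations" matched as one mention, not "heart" + "palpitations"
  expect_true("heart palpitation" %in% got$lemma)
  expect_false("heart" %in% got$lemma)
  # roles
  expect_equal(m$role[m$lemma == "avelox"], "effective")
  expect_equal(m$role[m$lemma == "confusion"], "affected")
  expect_equal(m$role[m$lemma == "course"], "other")
})

test_that("longest match suppresses contained shorter terms", {
  u <- prep_units(list(drug = "Accutane", benefits = "reduced amount of cystic acne"))
  m <- tag_entities(u, example_lexicon(), affected_groups = "DISO")
  expect_true("cystic acne" %in% m$lemma)
  expect_false("acne" %in% m$lemma)
})

test_that("empty unit yields no mentions; unknown terms stay untagged", {
  u <- prep_units(list(drug = "Advil", benefits = "Nothing whatsoever happened."))
  m <- tag_entities(u, example_lexicon(), affected_groups = "DISO")
  expect_equal(nrow(m), 0)
})

test_that("SGF-IOF matches the closed form on hand counts", {
  dom <- tibble::tibble(sem_group = c("DISO", "CONC"), n = c(5L, 5L))
  bg <- tibble::tibble(sem_group = c("DISO", "CONC"), n = c(15L, 75L))
  w <- compute_sgf_iof(dom, bg, alpha = 0.4)
  # DISO: (5/10) * ln(0.4 * 100 / 20)
  expect_equal(w$weight[w$sem_group == "DISO"], 0.5 * log(2), tolerance = 1e-15)
  expect_equal(w$weight[w$sem_group == "DISO"], 0.34657, tolerance = 1e-4)
  # alpha * sum == n_sg  =>  log(1) = 0
  w2 <- compute_sgf_iof(
    tibble::tibble(sem_group = "A", n = 4L),
    tibble::tibble(sem_group = c("A", "B"), n = c(36L, 60L)),
    alpha = 0.4
  )
  expect_identical(w2$weight[w2$sem_group == "A"], 0)
})

test_that("SGF-IOF agrees with a brute-force oracle on random count tables", {
  brute <- function(dom, bg, alpha) {
    groups <- union(dom$sem_group, bg$sem_group)
    whole <- sapply(groups, function(g) {
      sum(dom$n[dom$sem_group == g]) + sum(bg$n[bg$sem_group == g])
    })
    sum_d <- sum(dom$n)
    sum_all <- sum(whole)
    sapply(groups, function(g) {
      n_d <- sum(dom$n[dom$sem_group == g])
      if (n_d == 0) {
        return(0)
      }
      (n_d / sum_d) * log(alpha * sum_all / whole[[g]])
    })
  }
  withr::with_seed(101, {
    for (rep in seq_len(1000)) {
      k <- sample(1:10, 1)
      groups <- paste0("G", seq_len(k))
      dom <- tibble::tibble(sem_group = groups, n = sample(0:1000, k, TRUE))
      bg <- tibble::tibble(sem_group = groups, n = sample(0:1000, k, TRUE))
      if (sum(dom$n) == 0) dom$n[1] <- 1L
      alpha <- stats::runif(1, 0.05, 2)
      w <- compute_sgf_iof(dom, bg, alpha = alpha)
      expected <- brute(dom, bg, alpha)
      got <- w$weight[match(names(expected), w$sem_group)]
      denom <- pmax(abs(expected), 1)
      expect_true(all(abs(got - expected) / denom < 1e-12))
    }
  })
})

test_that("SGF-IOF weight is monotone in the domain count and antitone in the whole-set count", {
  # hold the whole-set counts fixed (pass them directly) and vary one margin
  w_at <- function(n_a_dom, n_a_whole) {
    dom <- tibble::tibble(sem_group = c("A", "B"), n = c(n_a_dom, 10L))
    whole <- tibble::tibble(sem_group = c("A", "B"), n = c(n_a_whole, 280L))
    w <- compute_sgf_iof(dom, whole, alpha = 0.4, include_domain = FALSE)
    w$weight[w$sem_group == "A"]
  }
  expect_true(w_at(2L, 20L) < w_at(5L, 20L))
  expect_true(w_at(5L, 20L) < w_at(9L, 20L))
  expect_true(w_at(5L, 20L) > w_at(5L, 60L))
})

test_that("SGF-IOF errors on empty or inconsistent domains", {
  expect_error(
    compute_sgf_iof(
      tibble::tibble(sem_group = "A", n = 0L),
      tibble::tibble(sem_group = "A", n = 5L)
    ),
    "empty domain"
  )
  expect_error(
    compute_sgf_iof(
      tibble::tibble(sem_group = "A", n = 5L),
      tibble::tibble(sem_group = "A", n = 3L),
      include_domain = FALSE
    ),
    "inconsistent|exceeds"
  )
})

test_that("group selection applies the theta threshold", {
  w <- compute_sgf_iof(
    tibble::tibble(sem_group = c("DISO", "CONC", "XTRA"), n = c(8L, 2L, 0L)),
    tibble::tibble(sem_group = c("DISO", "CONC", "XTRA"), n = c(2L, 88L, 10L))
  )
  expect_equal(select_affected_groups(w, theta = 0.084), "DISO")
  expect_warning(sel <- select_affected_groups(w, theta = 10), "no semantic group")
  expect_length(sel, 0)
  # theta = 0: every group with non-negative weight, including zero-frequency
  # groups (weight exactly 0); negative-weight groups still drop out
  expect_setequal(select_affected_groups(w, theta = 0), c("DISO", "XTRA"))
})

test_that("effective entities are always drug-typed under the default lexicon", {
  fix <- generate_fixtures(sim_config(seed = 13, n_reviews = 25))
  res <- build_opinion_resources(
    fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
  )
  eff <- res$mentions[res$mentions$role == "effective", ]
  expect_true(all(eff$sem_group == "CHEM"))
  drug_terms <- fix$lexicon$term[fix$lexicon$sem_type == "phsu"]
  expect_true(all(tolower(res$quadruples$effective) %in% drug_terms))
})
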