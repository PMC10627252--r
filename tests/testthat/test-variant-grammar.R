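test_that("printed suffix examples parse into the expected structures", {
  f <- parse_variant_suffix("+")
  expect_identical(f[[1]]$type, "wild_type")

  f <- parse_variant_suffix("Δ(114-120,150-200)")
  expect_identical(f[[1]]$type, "partial_deletion")
  expect_identical(f[[1]]$mode, "removed")
  expect_equal(unname(f[[1]]$ranges[, 1]), c(114L, 150L))
  expect_equal(unname(f[[1]]$ranges[, 2]), c(120L, 200L))

  f <- parse_variant_suffix("-P114A,Q117A")
  e <- f[[1]]$edits
  expect_length(e, 2)
  expect_identical(e[[1]]$replaced, "P")
  expect_identical(e[[1]]$position, 114L)
  expect_identical(e[[1]]$replacement, "A")
  expect_identical(e[[1]]$kind, "substitution")
  expect_identical(e[[2]]$replaced, "Q")

  # deletion-insertion vs consecutive substitution vs insertion
  f <- parse_variant_suffix("-PLI114LAVKK")
  expect_identical(f[[1]]$edits[[1]]$kind, "deletion_insertion")
  expect_identical(parse_variant_suffix("-PLI114AAA")[[1]]$edits[[1]]$kind,
                   "substitution")
  e <- parse_variant_suffix("-P114PVAL")[[1]]$edits[[1]]
  expect_identical(e$kind, "insertion")
  e <- parse_variant_suffix("-P114*")[[1]]$edits[[1]]
  expect_identical(e$kind, "nonsense")

  # short-name fallback is legal, with an info note
  f <- parse_variant_suffix("-35")
  expect_identical(f[[1]]$type, "short_name")
  expect_identical(f[[1]]$text, "35")
  expect_true("short_name" %in% attr(f, "lints")$code)
})

test_that("CTD blocks parse with selectors, in-repeat deletions and order", {
  items <- parse_ctd_suffix("Y1F")
  expect_length(items, 1)
  expect_identical(items[[1]]$op, "edit")
  expect_identical(items[[1]]$edit$replaced, "Y")
  expect_length(items[[1]]$selectors, 0)

  items <- parse_ctd_suffix("Δ(r11-r29)")
  expect_identical(items[[1]]$op, "delete_repeat")
  expect_identical(items[[1]]$selectors[[1]]$start, 11L)
  expect_identical(items[[1]]$selectors[[1]]$end, 29L)

  items <- parse_ctd_suffix("S5A(r1-r12),Δ(r13-r29)")
  expect_length(items, 2)
  expect_identical(items[[1]]$op, "edit")
  expect_identical(items[[2]]$op, "delete_repeat")

  # comma list form of selectors
  items <- parse_ctd_suffix("Y1F(r1,r2)")
  expect_length(items[[1]]$selectors, 2)

  expect_error(parse_ctd_suffix("Y1F(r0)"), class = "pombelint_parse_error")
  expect_error(parse_ctd_suffix("Y1F(r1-r5-0)"), class = "pombelint_parse_error")
  # the CTD block must come last when serializing
  expect_error(
    serialize_variant_features(list(
      parse_variant_suffix("-CTD-Y1F")[[1]],
      parse_variant_suffix("-P114A")[[1]]
    )),
    class = "pombelint_parse_error")
})

test_that("selector expansion equals brute-force membership", {
  expect_identical(
    expand_ctd_selectors(list(list(start = 1, end = 29, step = 2)), 29),
    seq(1L, 29L, 2L))
  expect_identical(
    expand_ctd_selectors(list(list(start = 1, end = 12, step = 1)), 29),
    1:12)
  expect_identical(expand_ctd_selectors(list(), 5), 1:5)
  expect_error(expand_ctd_selectors(list(list(start = 1, end = 40, step = 1)), 29),
               class = "pombelint_parse_error")

  brute <- function(sels, n) {
    hit <- logical(n)
    for (i in seq_len(n)) {
      for (s in sels) {
        end <- if (is.na(s$end)) s$start else s$end
        if (i >= s$start && i <= end && (i - s$start) %% s$step == 0) {
          hit[i] <- TRUE
        }
      }
    }
    which(hit)
  }
  withr::with_seed(21, {
    for (rep in 1:1000) {
      n <- sample(5:40, 1)
      sels <- replicate(sample(1:3, 1), {
        a <- sample.int(n, 1)
        b <- if (runif(1) < 0.4) NA_integer_ else min(n, a + sample.int(10, 1))
        list(start = a, end = b, step = if (is.na(b)) 1L else sample.int(3, 1))
      }, simplify = FALSE)
      expect_identical(expand_ctd_selectors(sels, n), brute(sels, n))
    }
  })
})

test_that("range complement matches printed equivalences and is an involution", {
  expect_equal(complement_ranges(rbind(c(1, 113)), 731),
               cbind(start = 114L, end = 731L))
  expect_equal(complement_ranges(rbind(c(20, 114), c(530, 731)), 731),
               cbind(start = c(1L, 115L), end = c(19L, 529L)))
  expect_equal(nrow(complement_ranges(rbind(c(1, 50)), 50)), 0)
  expect_error(complement_ranges(rbind(c(1, 800)), 731),
               class = "pombelint_parse_error")
  expect_error(complement_ranges(rbind(c(20, 10)), 731),
               class = "pombelint_parse_error")

  withr::with_seed(22, {
    for (rep in 1:500) {
      L <- sample(20:1000, 1)
      k <- sample(1:4, 1)
      bounds <- sort(sample.int(L, 2 * k))
      m <- cbind(bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)])
      m <- m[!duplicated(m[, 1]) & m[, 1] <= m[, 2], , drop = FALSE]
      # canonical ranges leave a gap: touching ranges would merge under
      # complementation and are never written that way
      keep <- c(TRUE, m[-1, 1] > m[-nrow(m), 2] + 1L)
      m <- m[keep, , drop = FALSE]
      comp <- complement_ranges(m, L)
      if (nrow(comp) > 0) {
        expect_equal(unname(complement_ranges(comp, L)),
                     unname(cbind(as.integer(m[, 1]), as.integer(m[, 2]))))
      }
      covered <- sum(m[, 2] - m[, 1] + 1)
      covered_c <- if (nrow(comp)) sum(comp[, 2] - comp[, 1] + 1) else 0
      expect_identical(as.integer(covered + covered_c), as.integer(L))
    }
  })
})

test_that("malformed suffixes fail with the right class of error", {
  # syntax: spaces, stray separators, mixed alphabet
  expect_error(parse_variant_suffix("- P114A"), class = "pombelint_parse_error")
  expect_error(parse_variant_suffix("-P114A,"), class = "pombelint_parse_error")
  expect_false(pombelint:::recognize_variant_suffix("-B114J"))
  # semantics: descending ranges, misplaced stop, overlapping edits
  expect_error(parse_variant_suffix("Δ(30-20)"),
               class = "pombelint_semantic_error")
  expect_error(parse_variant_suffix("-P114*A"),
               class = "pombelint_semantic_error")
  expect_error(parse_variant_suffix("-PLI114AAA,L115F"),
               class = "pombelint_semantic_error")
  # RNA genes use DNA letters: an amino-acid-only edit list is rejected
  # (a single letters+digits token would fall back to a legal short name)
  expect_error(parse_variant_suffix("-G57S,C3A", product_kind = "rna"),
               class = "pombelint_parse_error")
  expect_identical(parse_variant_suffix("-G57S", product_kind = "rna")[[1]]$type,
                   "short_name")
  f <- parse_variant_suffix("-G57T", product_kind = "rna")
  expect_identical(f[[1]]$edits[[1]]$replacement, "T")
  # underscore in a short name is an error-severity finding
  f <- parse_variant_suffix("-x_1")
  expect_true("underscore_in_name" %in% attr(f, "lints")$code)
})

test_that("serialize and parse are mutually inverse on suffixes", {
  canonical <- c("+", "Δ", "(1-35)", "Δ(114-120,150-200)", "-P114A,Q117A",
                 "-PLI114LAVKK", "Δ(20-30)-P114A,E126A", "-CTD-Y1F",
                 "-CTD-S5A(r1-r12),Δ(r13-r29)", "-N494D-CTD-Y1F(r1-r12)",
                 "-35", "-CTD-Y1F(r1-r29-2)")
  for (s in canonical) {
    expect_identical(serialize_variant_features(parse_variant_suffix(s)), s)
  }
  withr::with_seed(23, {
    for (i in 1:500) {
      s <- rand_valid_suffix()
      f <- tryCatch(parse_variant_suffix(s),
                    pombelint_parse_error = function(e) NULL)
      if (is.null(f)) next  # random draw violated a semantic constraint
      expect_identical(serialize_variant_features(f), s)
      f2 <- parse_variant_suffix(serialize_variant_features(f))
      expect_identical(lapply(f2, unclass), lapply(f, unclass))
    }
  })
})

test_that("the assembled recognizer agrees with the structured parser", {
  corpus <- rand_suffix_corpus(2000, seed = 24)
  by_regex <- variant_suffix_matches(corpus)
  by_parser <- vapply(corpus, pombelint:::recognize_variant_suffix, TRUE,
                      USE.NAMES = FALSE)
  disagree <- corpus[by_regex != by_parser]
  expect_identical(disagree, character(0))
  # and both accept every printed example suffix
  printed <- c("+", "Δ", "(1-35)", "(1-35,40-700)", "Δ(114-120)",
               "Δ(114-120,150-200)", "-P114PVPAL", "-P114A,Q117A", "-P114*",
               "-PLI114AAA", "-PLI114LAVKK", "-CTD-Y1F", "-CTD-Y1F(r1-r12)",
               "-CTD-Δ(r11-r29)", "-CTD-Y1F(r1-r29-2)",
               "-CTD-S5A(r1-r12),Δ(r13-r29)", "-N494D-CTD-Δ(r11-r29)")
  expect_true(all(variant_suffix_matches(printed)))
  expect_true(all(vapply(printed, pombelint:::recognize_variant_suffix, TRUE)))
})

test_that("the shipped pattern table matches the printed example suffixes", {
  tab <- variant_regex_table()
  pat <- function(name) tab$pattern[tab$name == name]
  anchored <- function(p, x) grepl(paste0("^(", p, ")$"), x, perl = TRUE)
  expect_true(anchored(pat("wild_type"), "+"))
  expect_true(anchored(pat("deletion"), "Δ"))
  expect_true(all(anchored(pat("partial_deletion_retained"),
                           c("(1-35)", "(1-35,40-700)"))))
  expect_true(all(anchored(pat("partial_deletion_removed"),
                           c("Δ(114-120)", "Δ(114-120,150-200)"))))
  expect_true(all(anchored(pat("edits"),
                           c("-P114PVPAL", "-P114A,Q117A", "-P114*",
                             "-PLI114AAA", "-PLI114LAVKK"))))
  expect_true(all(anchored(pat("ctd"),
                           c("-CTD-Y1F", "-CTD-Y1F(r1-r12)", "-CTD-Δ(r11-r29)",
                             "-CTD-Y1F(r1-r29-2)", "-CTD-S5A(r1-r12),Δ(r13-r29)",
                             "-N494D-CTD-Δ(r11-r29)"))))
  expect_false(anchored(pat("edits"), "-P114A,"))
  expect_false(anchored(pat("partial_deletion_retained"), "(1-35,)"))
})
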