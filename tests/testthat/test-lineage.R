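# Sulston nomenclature: parsing, parent/daughter algebra, wildcard search

test_that("names parse with longest-founder-prefix rule", {
  p <- parseLineageName(c("ABal", "EMS", "Ea", "MSpp", "P2", "Z2",
                          "polar body", "ABq", "Emsa"))
  expect_identical(p$founder[1:6], c("AB", "EMS", "E", "MS", "P2", "Z2"))
  expect_identical(p$suffix[1:4], c("al", "", "a", "pp"))
  # EMS is a founder, not E + "ms" ('m', 's' are not division letters)
  expect_identical(p$founder[2L], "EMS")
  expect_false(p$parseable[7L])   # literal label
  expect_false(p$parseable[8L])   # 'q' is not a division letter
  expect_false(p$parseable[9L])   # case matters
})

test_that("parentOf strips letters and follows the founder pedigree", {
  expect_identical(parentOf("ABal"), "ABa")
  expect_identical(parentOf("MS"), "EMS")
  expect_identical(parentOf(c("Cap", "E", "Z3")), c("Ca", "EMS", "P4"))
  expect_true(is.na(parentOf("P0")))                 # root, silent
  expect_warning(res <- parentOf("polar body"), "unknown")
  expect_true(is.na(res))                            # literal, warned
})

test_that("daughtersOf inverts the pedigree and enumerates potentials", {
  expect_identical(daughtersOf("P2"), c("C", "P3"))
  expect_identical(daughtersOf("P0"), c("AB", "P1"))
  expect_identical(daughtersOf("EMS"), c("MS", "E"))
  expect_identical(daughtersOf("Z2"), character())
  pot <- daughtersOf("ABa")
  expect_setequal(pot, paste0("ABa", c("a", "p", "l", "r", "d", "v")))
  expect_true(attr(pot, "potential"))
  expect_setequal(daughtersOf("Ca", observed = c("Caa", "Cap", "Cpp")),
                  c("Caa", "Cap"))
  expect_warning(expect_length(daughtersOf("Nuc12"), 0), "unknown")
})

test_that("parent/daughter duality holds over enumerated names", {
  # exhaustive over all six division letters to depth 3 under each
  # letter-dividing founder, plus the founder pedigree itself
  names_all <- names(embryoTrace:::.FOUNDER_DAUGHTERS)
  for (f in LETTER_FOUNDERS) {
    frontier <- f
    for (g in 1:3) {
      frontier <- as.vector(outer(frontier, DIV_LETTERS, paste0))
      names_all <- c(names_all, frontier)
    }
  }
  for (nm in names_all) {
    par <- suppressWarnings(parentOf(nm))
    if (is.na(par)) next
    expect_true(nm %in% daughtersOf(par),
                label = sprintf("%s in daughtersOf(%s)", nm, par))
  }
})

test_that("isDescendant follows parent chains across founders", {
  expect_true(isDescendant("ABalp", "AB"))
  expect_false(isDescendant("MS", "AB"))
  expect_true(isDescendant("Cap", "P2"))   # Cap -> Ca -> C -> P2
  expect_true(isDescendant("Ea", "P1"))
  expect_true(isDescendant("ABa", "ABa"))
  expect_false(isDescendant("ABa", "ABa", inclusive = FALSE))
  expect_true(isDescendant("ABaa", "ABa", inclusive = FALSE))
  expect_warning(expect_false(isDescendant("Nuc9", "AB")), "unknown")
})

test_that("wildcard patterns match exactly one division letter", {
  expect_true(matchLineage("Cap", "Cxp"))
  expect_true(matchLineage("Cpp", "Cxp"))
  expect_false(matchLineage("Ca", "Cxp"))      # length mismatch
  expect_false(matchLineage("Capp", "Cxp"))
  expect_false(matchLineage("MSap", "Cxp"))    # founder mismatch
  expect_equal(matchLineage(c("Caaa", "Cpaa", "Capa"), "Cxaa"),
               c(TRUE, TRUE, FALSE))
  expect_false(matchLineage("polar body", "Cxp"))
  expect_error(matchLineage("Cap", "C?p"), "invalid")
})

test_that("patterns without wildcards reduce to exact equality", {
  set.seed(42)
  pool <- as.vector(outer(c("AB", "MS", "C"),
                          c("", "a", "p", "ap", "pl", "apl"), paste0))
  for (pat in sample(pool, 8)) {
    m <- matchLineage(pool, pat)
    expect_identical(pool[m], pat)
  }
})

test_that("selectCells unions patterns and expands descendants", {
  obs <- c("Ca", "Cp", "Cap", "Cpp", "Capa")
  expect_identical(selectCells(obs, "Cxp"), c("Cap", "Cpp"))
  expect_identical(selectCells(obs, "Cxp", includeDescendants = TRUE),
                   c("Cap", "Capa", "Cpp"))
  expect_identical(selectCells(obs, character()), character())
  expect_warning(res <- selectCells(obs, c("Cxp", "MSxx")), "MSxx")
  expect_identical(res, c("Cap", "Cpp"))

  # monotone in includeDescendants, order-independent
  for (seed in 31:33) {
    tb <- randomEmbryoTable(seed)
    pats <- c("Cx", "MSx")
    narrow <- suppressWarnings(selectCells(tb, pats))
    wide <- suppressWarnings(selectCells(tb, pats, TRUE))
    expect_true(all(narrow %in% wide))
    expect_identical(
      suppressWarnings(selectCells(rev(cellNames(tb)), pats, TRUE)), wide)
  }
})

test_that("wildcard expansion agrees with a regex oracle on observed sets", {
  set.seed(7)
  for (rep in 1:50) {
    obs <- cellNames(randomEmbryoTable(rep + 100))
    founder <- sample(LETTER_FOUNDERS, 1)
    sfx <- paste(sample(c(DIV_LETTERS, "x", "x"), sample(1:3, 1), TRUE),
                 collapse = "")
    pat <- paste0(founder, sfx)
    rx <- paste0("^", founder, gsub("x", "[apdvlr]", sfx), "$")
    oracle <- sort(obs[grepl(rx, obs) & isLineageName(obs)])
    expect_identical(suppressWarnings(selectCells(obs, pat)), oracle,
                     label = sprintf("pattern %s", pat))
  }
})
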