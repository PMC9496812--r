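test_that("parsing honours wildcard, classes, grouping; render round-trips", {
  ex <- parse_term_expression(
    "Family and (Med* or Clinic or Centre or Center or Associate* or Care or Practice)")
  expect_equal(ex$ast$op, "and")
  expect_equal(ex$ast$args[[2]]$op, "or")
  rendered <- render_term_expression(ex)
  expect_identical(parse_term_expression(rendered)$ast,
                   parse_term_expression(rendered)$ast)
  strip <- function(n) {
    n$regex <- NULL
    if (!is.null(n$args)) n$args <- lapply(n$args, strip)
    n
  }
  expect_identical(strip(parse_term_expression(rendered)$ast), ex$ast)

  expect_error(parse_term_expression("Wom[a,en*"), "position")
  expect_error(parse_term_expression("(A or B"), "bracket|\\)")
  expect_error(parse_term_expression("A or or B"), "unexpected")
  expect_error(parse_term_expression(""), "empty")
})

test_that("the anchored vocabulary examples behave as documented", {
  cr <- default_criteria()
  m <- function(name, text) evaluate_criterion(cr[[name]], text)$matched
  # Wom[a,e]n* expands to Woman*/Women* — possessives match, "Womb" does not
  expect_true(m("womens_health", "Women's Health Centre"))
  expect_true(m("womens_health", "Woman Care"))
  expect_false(m("womens_health", "Womb House"))
  # Family needs a practice-like companion term
  expect_true(m("family", "Family Practice Associates"))
  expect_false(m("family", "Smith Family Chiropractic"))
  # Hosp* catches hospitals and, notoriously, hospices
  expect_true(m("hospital", "General Hospital"))
  expect_true(m("hospital", "Hospice House"))
  # Tele* and the optional-hyphen classes
  expect_true(m("virtual", "Tele-Dermatology Office"))
  expect_true(m("virtual", "Provincial EHealth Office"))
  expect_true(m("virtual", "Provincial E-Health Office"))
  # multi-token administrative phrases with embedded wildcards
  expect_true(m("administrative", "WorkSafeBC Claims Office"))
  expect_true(m("administrative", "Workers Compensation Board"))
  expect_true(m("administrative", "College of Physicians and Surgeons"))
  # token boundaries: atoms never fire mid-word
  expect_false(m("family", "Scared Family"))   # "Care" not inside "Scared"
  expect_false(m("clinic_center", "Indoctor8 Lab"))
  # phrase atom must be contiguous
  expect_true(m("clinic_center", "Centre of Practice"))
  expect_false(m("clinic_center", "Centre for the Practice"))
  # empty text never matches
  for (nm in names(cr)) {
    expect_false(evaluate_criterion(cr[[nm]], "")$matched)
  }
})

test_that("strict hyphen mode requires the literal hyphen", {
  strict <- term_criterion("virtual", "exclude",
                           "Virtual or E[-]Health or Tele* or I[-]Health",
                           strict_hyphen = TRUE)
  expect_true(evaluate_criterion(strict, "E-Health Portal")$matched)
  expect_false(evaluate_criterion(strict, "EHealth Portal")$matched)
})

test_that("matching is deterministic and fired atoms form the audit trail", {
  cr <- default_criteria()
  r1 <- evaluate_criterion(cr$administrative, "WorkSafeBC Claims Office")
  r2 <- evaluate_criterion(cr$administrative, "WorkSafeBC Claims Office")
  expect_identical(r1, r2)
  expect_true(r1$matched)
  expect_gt(nrow(r1$fired_atoms), 0)
  expect_true(all(r1$fired_atoms$criterion == "administrative"))
  expect_true("worksafebc" %in% r1$fired_atoms$span)
})

test_that("name-list entries match as case-insensitive whole phrases", {
  cr <- term_criterion("first_nations", "include",
                       "First Nation* or Indigenous",
                       name_list = c("Raven Song Wellness"))
  expect_true(evaluate_criterion(cr, "RAVEN SONG WELLNESS centre")$matched)
  expect_false(evaluate_criterion(cr, "Raven Song")$matched)
  r <- evaluate_criterion(cr, "Raven Song Wellness")
  expect_true(any(grepl("Raven", r$fired_atoms$atom)))
})

test_that("adding an or-atom is monotone: matches never become non-matches", {
  set.seed(101)
  for (i in 1:40) {
    base <- random_expression()
    wider <- paste0(base, " or ", random_atom())
    crit_base <- term_criterion("x", "include", base)
    crit_wide <- term_criterion("x", "include", wider)
    for (j in 1:10) {
      s <- random_corpus_string()
      if (evaluate_criterion(crit_base, s)$matched) {
        expect_true(evaluate_criterion(crit_wide, s)$matched)
      }
    }
  }
})

test_that("evaluator agrees with the brute-force expansion oracle", {
  set.seed(202)
  n_expr <- 25
  n_str <- 80
  for (i in seq_len(n_expr)) {
    src <- random_expression()
    crit <- term_criterion("x", "include", src)
    for (j in seq_len(n_str)) {
      s <- random_corpus_string()
      expect_identical(evaluate_criterion(crit, s)$matched,
                       oracle_matches(src, s),
                       label = paste0("expr=<", src, "> text=<", s, ">"))
    }
  }
  # no-wildcard expressions also agree with plain token-anchored search
  plain <- term_criterion("x", "include", "ab or cd")
  for (s in c("ab", "xx ab", "dab", "cda", "cd-x", "abc")) {
    expect_identical(evaluate_criterion(plain, s)$matched,
                     oracle_matches("ab or cd", s))
  }
  # two-way class expansion, enumerated exhaustively
  for (s in c("woman", "women", "womenx", "womn", "wimen")) {
    expect_identical(evaluate_criterion(
      term_criterion("x", "include", "Wom[a,e]n*"), s)$matched,
      s %in% c("woman", "women", "womenx"))
  }
})
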