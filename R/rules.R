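#' Classification rule sets
#'
#' The three food-category classifiers are driven by editable keyword lists:
#' fast-food chain names, soda brand names, soda excluder tokens, fresh
#' fruit & vegetable terms, and F&V excluder tokens (juice-type terms).
#' All keywords are stored pre-normalized (lowercase, punctuation-free).
#'
#' The fruit & vegetable list follows a MyPlate-style inventory of fresh
#' produce with juices deliberately excluded; it is an editable
#' approximation maintained as configuration, not code.
#'
#' @param dir Directory containing the five rule files
#'   (`fastfood_chains.txt`, `soda_names.txt`, `soda_excluders.txt`,
#'   `fv_keywords.txt`, `fv_excluders.txt`), one keyword per line, `#`
#'   comments allowed. Defaults to the rule files shipped with the package.
#' @return An object of class `ruleset`: a list with elements
#'   `fastfood_chains`, `soda_names`, `soda_excluders`, `fv_keywords`,
#'   `fv_excluders`, each a character vector of normalized keywords.
#' @export
#' @examples
#' rules <- load_rules()
#' head(rules$fastfood_chains)
load_rules <- function(dir = system.file("extdata", "rules", package = "dietscape")) {
  read_kw <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop("rule file not found: ", path, call. = FALSE)
    }
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- trimws(x)
    x <- x[nzchar(x) & !startsWith(x, "#")]
    normalize_text(x)
  }
  rules <- structure(
    list(
      fastfood_chains = read_kw("fastfood_chains.txt"),
      soda_names      = read_kw("soda_names.txt"),
      soda_excluders  = read_kw("soda_excluders.txt"),
      fv_keywords     = read_kw("fv_keywords.txt"),
      fv_excluders    = read_kw("fv_excluders.txt")
    ),
    class = "ruleset"
  )
  validate_rules(rules)
  rules
}

#' Validate a classification rule set
#'
#' Checks the structural invariants: all five lists present and non-empty,
#' keywords already normalized, and the soda excluders containing at least
#' the four mandatory tokens (diet, lite, light, zero).
#'
#' @param rules A `ruleset` (see [load_rules()]).
#' @return `rules`, invisibly, if valid; otherwise an error.
#' @export
validate_rules <- function(rules) {
  required <- c("fastfood_chains", "soda_names", "soda_excluders",
                "fv_keywords", "fv_excluders")
  if (!is.list(rules) || !all(required %in% names(rules))) {
    stop("invalid RuleSet: expected lists ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  for (nm in required) {
    kw <- rules[[nm]]
    if (!is.character(kw) || length(kw) == 0) {
      stop("invalid RuleSet: '", nm, "' must be a non-empty character vector",
           call. = FALSE)
    }
    if (!identical(kw, normalize_text(kw))) {
      stop("invalid RuleSet: '", nm, "' contains non-normalized keywords",
           call. = FALSE)
    }
  }
  mandatory <- c("diet", "lite", "light", "zero")
  if (!all(mandatory %in% rules$soda_excluders)) {
    stop("invalid RuleSet: soda_excluders must include ",
         paste(mandatory, collapse = ", "), call. = FALSE)
  }
  invisible(rules)
}
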