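# shared internal helpers: tokenisation, seeding, small validators

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize text for featurisation
#'
#' Lowercases, replaces every non-alphanumeric character with a space and
#' splits on whitespace. This is the single tokenisation rule used by the
#' tf-idf and embedding extractors and by the corpus descriptives, so word
#' counts and feature vocabularies agree.
#'
#' @param x character vector.
#' @param remove_stopwords drop common English function words.
#' @return list of character vectors, one per element of `x`.
#' @export
tokenize_text <- function(x, remove_stopwords = FALSE) {
  x <- tolower(ifelse(is.na(x), "", x))
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +", fixed = FALSE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (remove_stopwords) {
    toks <- lapply(toks, function(t) t[!(t %in% english_stopwords)])
  }
  toks
}

# compact English function-word list used by the tf-idf default config
english_stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "could", "did",
  "do", "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
  "just", "me", "more", "most", "my", "myself", "no", "nor", "not", "now",
  "of", "off", "on", "once", "only", "or", "other", "our", "ours", "out",
  "over", "own", "s", "same", "she", "should", "so", "some", "such", "t",
  "than", "that", "the", "their", "theirs", "them", "then", "there",
  "these", "they", "this", "those", "through", "to", "too", "under",
  "until", "up", "very", "was", "we", "were", "what", "when", "where",
  "which", "while", "who", "whom", "why", "will", "with", "would", "you",
  "your", "yours"
)

# deterministic per-step seed stream; keeps every derived seed < 2^31
derive_seed <- function(seed, step) {
  as.integer((as.numeric(seed) * 131071 + as.numeric(step)) %% 2147483629)
}

# seed the generator with an explicit, version-stable algorithm so that
# identical specs reproduce byte-identical output across platforms
set_seed_stable <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}
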