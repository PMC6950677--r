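#' Normalize Portuguese label text for matching
#'
#' Lowercases and accent-folds (á→a, ç→c, …) so that "AÇÚCAR", "açúcar" and
#' "acucar" compare equal. Folding is done with an explicit character map,
#' not locale transliteration, so results are identical on any system.
#'
#' @param x Character vector.
#' @return Folded character vector.
#' @export
fold_pt <- function(x) {
  x <- chartr(
    "áàâãäéèêëíìîïóòôõöúùûüçñÁÀÂÃÄÉÈÊËÍÌÎÏÓÒÔÕÖÚÙÛÜÇÑ",
    "aaaaaeeeeiiiiooooouuuucnAAAAAEEEEIIIIOOOOOUUUUCN",
    as.character(x)
  )
  tolower(x)
}

#' @keywords internal
#' Padded token string: " farinha de trigo acucar sal ". Single- and
#' multi-word keywords both reduce to fixed substring search of " kw ".
token_string <- function(x) {
  x <- fold_pt(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  paste0(" ", trimws(x), " ")
}

#' @keywords internal
tokenize_pt <- function(x) {
  strsplit(trimws(gsub("[^a-z0-9]+", " ", fold_pt(x))), " ", fixed = TRUE)
}

#' Ingredient keyword lexicon
#'
#' The four Portuguese keyword sets used to flag added sugar, added salt,
#' added fat, and nonnutritive sweeteners in ingredient lists. The default
#' lexicon ships as an editable YAML file
#' (`system.file("extdata", "ingredient_lexicon.yml", package = "foplabel")`);
#' its terms are a reconstruction in Portuguese of the documented English
#' keyword glosses (sugar, honey, syrups, molasses, maltodextrin, glucose,
#' fructose, concentrated fruit/vegetable juices, chocolate, milk fondant;
#' salt, sodium chloride, cheeses, processed meats; oils, olives, butter,
#' creams, animal/vegetable fats; and the named nonnutritive sweeteners) and
#' is versioned as such. Lexicons store stems plus explicit plural forms; no
#' stemming is applied, which keeps matching auditable.
#'
#' @param path Path to a lexicon YAML file (keys `version`, `sugar`, `salt`,
#'   `fat`, `nns`).
#' @return A lexicon: list with `version` and four character vectors.
#' @export
read_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  for (cl in c("sugar", "salt", "fat", "nns")) {
    if (is.null(lex[[cl]])) {
      stop("lexicon file lacks keyword set '", cl, "': ", path, call. = FALSE)
    }
    lex[[cl]] <- as.character(unlist(lex[[cl]]))
  }
  lex
}

#' @rdname read_lexicon
#' @export
default_ingredient_lexicon <- function() {
  read_lexicon(
    system.file("extdata", "ingredient_lexicon.yml",
      package = "foplabel", mustWork = TRUE
    )
  )
}

#' Validate an ingredient lexicon
#'
#' Reports empty or non-string terms (errors), duplicate terms within a set
#' and cross-set collisions (warnings), comparing terms after normalization
#' with [fold_pt()].
#'
#' @param lexicon A lexicon list as returned by [read_lexicon()].
#' @return Tibble with columns `level` ("error"/"warning"), `set`, `term`,
#'   `message`; zero rows for a clean lexicon.
#' @export
validate_lexicon <- function(lexicon) {
  sets <- c("sugar", "salt", "fat", "nns")
  out <- list()
  add <- function(level, set, term, msg) {
    out[[length(out) + 1]] <<- tibble::tibble(
      level = level, set = set, term = term, message = msg
    )
  }
  for (cl in sets) {
    terms <- lexicon[[cl]]
    if (is.null(terms)) {
      add("error", cl, NA_character_, "keyword set missing")
      next
    }
    bad <- is.na(terms) | !nzchar(trimws(terms))
    for (tm in terms[bad]) add("error", cl, tm, "empty term")
    norm <- token_string(terms[!bad])
    dup <- duplicated(norm)
    for (tm in terms[!bad][dup]) add("warning", cl, tm, "duplicate term in set")
  }
  norm_sets <- lapply(sets, function(cl) unique(token_string(lexicon[[cl]])))
  names(norm_sets) <- sets
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j) {
        coll <- intersect(norm_sets[[i]], norm_sets[[j]])
        for (tm in coll) {
          add(
            "warning", sets[i], trimws(tm),
            paste0("term also present in set '", sets[j], "'")
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(
      level = character(0), set = character(0),
      term = character(0), message = character(0)
    )
  } else {
    dplyr::bind_rows(out)
  }
}

#' Screen ingredient lists for added critical nutrients
#'
#' Flags each ingredient list for added sugar, added salt, added fat, and
#' nonnutritive sweeteners by keyword search. Matching contract: both text
#' and keywords are lowercased and accent-folded, then tokenized on
#' non-letter/digit boundaries; single-word keywords match whole tokens only
#' (so "salsa" never triggers "sal") and multi-word keywords match
#' contiguous token runs. Empty text yields all-false flags.
#'
#' @param texts Character vector of ingredient lists (free Portuguese text).
#' @param lexicon A keyword lexicon ([default_ingredient_lexicon()]).
#' @param collect_matches Record, per text, which keyword matched where
#'   (token position of the keyword's first token). Turn off in bulk
#'   simulation for speed.
#' @return Tibble with one row per text: logical `added_sugar`,
#'   `added_salt`, `added_fat`, `nns`, and (if requested) a `matches`
#'   list-column of tibbles `(set, keyword, position)`.
#' @export
#' @examples
#' lex <- default_ingredient_lexicon()
#' screen_ingredients("farinha de trigo, açúcar, sal", lex)
screen_ingredients <- function(texts, lexicon = default_ingredient_lexicon(),
                               collect_matches = TRUE) {
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  padded <- token_string(texts)
  sets <- c(
    added_sugar = "sugar", added_salt = "salt",
    added_fat = "fat", nns = "nns"
  )
  n <- length(texts)
  flags <- list()
  hit_detail <- if (collect_matches) vector("list", n) else NULL
  for (k in seq_along(sets)) {
    terms <- lexicon[[sets[[k]]]]
    needles <- token_string(terms)
    any_hit <- rep(FALSE, n)
    for (t in seq_along(needles)) {
      hit <- grepl(needles[t], padded, fixed = TRUE)
      if (collect_matches && any(hit)) {
        pos <- regexpr(needles[t], padded[hit], fixed = TRUE)
        tokpos <- vapply(seq_along(pos), function(i) {
          prefix <- substr(padded[hit][i], 1, pos[i])
          lengths(regmatches(prefix, gregexpr(" ", prefix, fixed = TRUE)))
        }, integer(1))
        det <- tibble::tibble(
          set = sets[[k]], keyword = terms[t], position = tokpos
        )
        idx <- which(hit)
        for (i in seq_along(idx)) {
          hit_detail[[idx[i]]] <- c(hit_detail[[idx[i]]], list(det[i, ]))
        }
      }
      any_hit <- any_hit | hit
    }
    flags[[names(sets)[k]]] <- any_hit
  }
  out <- tibble::as_tibble(flags)
  if (collect_matches) {
    out$matches <- lapply(hit_detail, function(d) {
      if (is.null(d)) {
        tibble::tibble(
          set = character(0), keyword = character(0), position = integer(0)
        )
      } else {
        dplyr::bind_rows(d)
      }
    })
  }
  out
}
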