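# shared fixtures, built in code

`%||%` <- function(x, y) if (is.null(x)) y else x

fixture_filter <- function() {
  search_filter(
    filter_keywords(
      term = c("vape", "vaping", "e-cig", "atomizer", "perfume",
               "vape pen", "#vapelife", "@blucigs"),
      category = c("behavior", "behavior", "device", "device",
                   "exclusion-helper", "device", "behavior", "brand"),
      mode = c("word", "word", "word", "word", "word",
               "phrase", "hashtag", "handle")
    ),
    exclusions = list(c("atomizer", "perfume"))
  )
}

# ten messages with a hand-computed expected partition
fixture_corpus <- function() {
  tibble::tibble(
    id = sprintf("m%02d", 1:10),
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + (1:10) * 3600,
    text = c(
      "loving my new vape pen so much",         # phrase match -> retrieved
      "best smoked brisket in town",            # no match
      "switched to an e-cig last week",         # word match -> retrieved
      "this atomizer perfume bottle is lovely", # veto pair -> excluded
      "my atomizer coil burned out",            # atomizer alone -> retrieved
      "monday traffic is unreal",               # no match
      "check out @blucigs for deals",           # handle mention -> retrieved
      "she is smoking hot in that dress",       # decoy, no keyword
      "vaping after lunch with friends",        # word match -> retrieved
      "new vapelife post is up"                 # hashtag mode, bare token
    ),
    author = c("u1", "u2", "u3", "u4", "u5", "u6", "u7", "u8", "u9", "u10")
  )
}

fixture_expected_retrieved <- c("m01", "m03", "m05", "m07", "m09", "m10")

# the published case-study inputs, used across modules
ecig_coded_sample <- function() confusion_table(4176, 197, 20, 6285)
ecig_adjusted_table <- function() confusion_table(128, 6, 20, 6285)
ecig_design <- function() stratified_design(4373, 6305, 82205, 3872370)
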