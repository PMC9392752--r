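#include <Rcpp.h>
using namespace Rcpp;

// One WCST session played by the four-parameter agent.
//
// The 64-card deck enumerates all colour x shape x size combinations with
// colour varying fastest (card k: colour = k %% 4, shape = (k/4) %% 4,
// size = (k/16) %% 4, attribute values coded 1..4).  The four target cards
// are the diagonal (v, v, v), v = 1..4, so the target matching a card on
// rule r is simply the card's r-th attribute value.
//
// Per trial: softmax selection on the current priorities (one uniform
// variate), card placement and feedback, then the updates in this order:
// motivational +/- mu on the selected rule, decay phi towards the baseline
// for all rules, inner-speech bias +/- lambda on the selected rule.  Each
// update clips to [0, 1].  All randomness comes from R's RNG stream so a
// set.seed() at the R level makes the session reproducible.

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Fisher-Yates shuffle of idx using unif_rand(), matching the pure-R engine.
static void shuffle_deck(std::vector<int>& idx) {
  const int n = (int)idx.size();
  for (int i = n - 1; i >= 1; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i; // unif_rand() == 1.0 guard
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".cpp_session")]]
List cpp_session(double mu, double phi, double tau, double lam,
                 int n_decks = 2, int criterion = 10, int max_categories = 6,
                 double baseline = 0.5) {
  const int deck_size = 64;
  const int n_cards = deck_size * n_decks;

  std::vector<int> deck(n_cards);
  for (int d = 0; d < n_decks; ++d) {
    std::vector<int> one(deck_size);
    for (int k = 0; k < deck_size; ++k) one[k] = k;
    shuffle_deck(one);
    for (int k = 0; k < deck_size; ++k) deck[d * deck_size + k] = one[k];
  }

  double p[3] = {baseline, baseline, baseline};
  int cur = 0;                // current sorting rule: 0 colour, 1 shape, 2 size
  int prev_rule = NA_INTEGER; // rule of the last completed category
  int prev_sel = -1;          // selection on the previous trial
  int run = 0;                // consecutive positive feedbacks in this category
  int cc = 0, pe = 0, npe = 0, fms = 0;

  IntegerMatrix cards(n_cards, 3);
  IntegerVector selected(n_cards), chosen(n_cards), rule_in_play(n_cards);
  LogicalVector positive(n_cards), fms_flag(n_cards);
  IntegerVector classification(n_cards); // 1 CR, 2 PE, 3 NPE
  NumericMatrix trace(n_cards, 3);

  int t = 0;
  for (; t < n_cards; ++t) {
    // attributes of the drawn card, 1..4 per category
    int k = deck[t];
    int attr[3] = {k % 4 + 1, (k / 4) % 4 + 1, (k / 16) % 4 + 1};
    cards(t, 0) = attr[0];
    cards(t, 1) = attr[1];
    cards(t, 2) = attr[2];
    trace(t, 0) = p[0];
    trace(t, 1) = p[1];
    trace(t, 2) = p[2];
    rule_in_play[t] = cur + 1;

    // softmax rule selection: exactly one uniform variate per trial
    double m = p[0];
    if (p[1] > m) m = p[1];
    if (p[2] > m) m = p[2];
    double w0 = std::exp((p[0] - m) / tau);
    double w1 = std::exp((p[1] - m) / tau);
    double w2 = std::exp((p[2] - m) / tau);
    double u = unif_rand() * ((w0 + w1) + w2);
    int sel = (u <= w0) ? 0 : ((u <= w0 + w1) ? 1 : 2);

    // placement and feedback ("lucky matches" on ambiguous cards count)
    bool pos = attr[sel] == attr[cur];
    selected[t] = sel + 1;
    chosen[t] = attr[sel];
    positive[t] = pos;

    // motivational update, decay, inner-speech bias
    p[sel] = clip01(p[sel] + (pos ? mu : -mu));
    for (int r = 0; r < 3; ++r) p[r] += phi * (baseline - p[r]);
    p[sel] = clip01(p[sel] + (pos ? lam : -lam));

    // scoring
    if (pos) {
      classification[t] = 1;
      fms_flag[t] = false;
      if (++run == criterion) {
        ++cc;
        prev_rule = cur;
        cur = (cur + 1) % 3;
        run = 0;
        if (cc == max_categories) { prev_sel = sel; ++t; break; }
      }
    } else {
      bool is_pe = (prev_sel >= 0) && (sel == prev_sel);
      classification[t] = is_pe ? 2 : 3;
      if (is_pe) ++pe; else ++npe;
      fms_flag[t] = (run >= 5) && (prev_sel >= 0) && (sel != prev_sel);
      if (fms_flag[t]) ++fms;
      run = 0;
    }
    prev_sel = sel;
  }

  Range kept(0, t - 1);
  return List::create(
      _["cards"] = cards(kept, _),
      _["rule_in_play"] = rule_in_play[kept],
      _["selected"] = selected[kept],
      _["chosen_target"] = chosen[kept],
      _["positive"] = positive[kept],
      _["classification"] = classification[kept],
      _["fms_flag"] = fms_flag[kept],
      _["trace"] = trace(kept, _),
      _["counts"] = IntegerVector::create(_["cc"] = cc, _["pe"] = pe,
                                          _["npe"] = npe, _["fms"] = fms),
      _["n_trials"] = t);
}

// Softmax rule sampler sharing the session's arithmetic; used to validate the
// selection distribution against its closed form.
// [[Rcpp::export(name = ".cpp_select_rule")]]
IntegerVector cpp_select_rule(NumericVector priorities, double tau, int n) {
  double m = std::max(priorities[0], std::max(priorities[1], priorities[2]));
  double w0 = std::exp((priorities[0] - m) / tau);
  double w1 = std::exp((priorities[1] - m) / tau);
  double w2 = std::exp((priorities[2] - m) / tau);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * ((w0 + w1) + w2);
    out[i] = (u <= w0) ? 1 : ((u <= w0 + w1) ? 2 : 3);
  }
  return out;
}
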