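#include <Rcpp.h>
using namespace Rcpp;

// Random partner matching for one ligation round.
//
// Eligible fragments (1-based indices into the fragment vector) are visited
// in random order; each initiates a ligation with probability
// ligation_rate. The partner is drawn uniformly from the union of the
// remaining eligible fragments and the remaining intact survivors, which
// weights the partner class by its current population size. Both molecules
// are consumed (no replacement); products do not react again this round.
// Uses R's RNG so results are reproducible under set.seed().
//
// Returns a 3-column integer matrix: initiator fragment index, partner
// fragment index (0 if the partner is a survivor), partner survivor index
// (0 if the partner is a fragment).
// [[Rcpp::export]]
IntegerMatrix ligation_matching(int n_frag, IntegerVector eligible,
                                int n_surv, double ligation_rate) {
  int nE = eligible.size();
  std::vector<int> availE(eligible.begin(), eligible.end());
  std::vector<int> posE(n_frag + 1, 0);      // 1-based slot, 0 = consumed
  for (int s = 0; s < nE; ++s) posE[availE[s]] = s + 1;
  std::vector<int> availS(n_surv);
  std::vector<int> posS(n_surv + 1, 0);
  for (int s = 0; s < n_surv; ++s) { availS[s] = s + 1; posS[s + 1] = s + 1; }
  int cntE = nE, cntS = n_surv;

  // random visiting order (Fisher-Yates)
  std::vector<int> order(eligible.begin(), eligible.end());
  for (int i = nE - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }

  std::vector<int> out_a, out_bE, out_bS;
  out_a.reserve(nE / 2); out_bE.reserve(nE / 2); out_bS.reserve(nE / 2);

  auto removeE = [&](int id) {
    int p = posE[id];
    int last = availE[cntE - 1];
    availE[p - 1] = last;
    posE[last] = p;
    posE[id] = 0;
    --cntE;
  };

  for (int i = 0; i < nE; ++i) {
    int id = order[i];
    if (posE[id] == 0) continue;          // consumed as a partner already
    if (unif_rand() >= ligation_rate) continue;
    int tot = (cntE - 1) + cntS;          // partner pool excludes initiator
    if (tot <= 0) continue;
    removeE(id);
    int u = (int)(unif_rand() * tot);
    if (u >= tot) u = tot - 1;
    if (u < cntE) {
      int partner = availE[u];
      removeE(partner);
      out_a.push_back(id); out_bE.push_back(partner); out_bS.push_back(0);
    } else {
      int p = u - cntE;                   // 0-based slot into availS
      int sid = availS[p];
      int last = availS[cntS - 1];
      availS[p] = last;
      posS[last] = p + 1;
      posS[sid] = 0;
      --cntS;
      out_a.push_back(id); out_bE.push_back(0); out_bS.push_back(sid);
    }
  }
  int k = out_a.size();
  IntegerMatrix res(k, 3);
  for (int i = 0; i < k; ++i) {
    res(i, 0) = out_a[i]; res(i, 1) = out_bE[i]; res(i, 2) = out_bS[i];
  }
  return res;
}
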