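#include <Rcpp.h>
using namespace Rcpp;

// Time-order randomization sweeps over a (pairId, step) event list.
// Each sweep visits every event in a freshly shuffled global order, draws a
// proposed slot t2 uniformly from 1..L and relocates the event iff its pair
// has no event at t2 (t2 equal to the current slot is occupied, hence
// rejected).  Uses R's RNG so set.seed() on the R side governs the stream.
// [[Rcpp::export]]
List shuffle_sweeps_cpp(IntegerVector pairId, IntegerVector step, int nPairs,
                        int L, int sweeps, bool record) {
  int nEvents = pairId.size();
  IntegerVector cur = clone(step);
  std::vector<std::vector<char> > occ(nPairs, std::vector<char>(L + 1, 0));
  for (int e = 0; e < nEvents; ++e) occ[pairId[e] - 1][cur[e]] = 1;

  std::vector<int> recPair, recFrom, recTo, recAcc;
  std::vector<int> order(nEvents);
  for (int e = 0; e < nEvents; ++e) order[e] = e;

  for (int s = 0; s < sweeps; ++s) {
    for (int e = nEvents - 1; e > 0; --e) {  // Fisher-Yates reshuffle
      int j = (int)(unif_rand() * (e + 1));
      if (j > e) j = e;
      std::swap(order[e], order[j]);
    }
    for (int idx = 0; idx < nEvents; ++idx) {
      int e = order[idx];
      int p = pairId[e] - 1;
      int t1 = cur[e];
      int t2 = (int)(unif_rand() * L) + 1;
      if (t2 > L) t2 = L;
      bool ok = !occ[p][t2];
      if (ok) {
        occ[p][t1] = 0;
        occ[p][t2] = 1;
        cur[e] = t2;
      }
      if (record) {
        recPair.push_back(p + 1);
        recFrom.push_back(t1);
        recTo.push_back(t2);
        recAcc.push_back(ok ? 1 : 0);
      }
    }
  }
  return List::create(_["step"] = cur,
                      _["rec_pair"] = wrap(recPair),
                      _["rec_from"] = wrap(recFrom),
                      _["rec_to"] = wrap(recTo),
                      _["rec_accepted"] = wrap(recAcc));
}
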