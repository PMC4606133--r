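#include <Rcpp.h>
#include <deque>
#include <set>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Upper-triangle bitstring: positions `pos` (1-based) set to '1' in a string
// of `len` '0's. Hot path of canonical labeling, hence C++.
// [[Rcpp::export(name = ".bitstring_cpp")]]
String bitstring_cpp(IntegerVector pos, int len) {
  std::string s(static_cast<size_t>(len), '0');
  for (int k : pos) {
    if (k < 1 || k > len) stop("bit position out of range");
    s[static_cast<size_t>(k - 1)] = '1';
  }
  return String(s);
}

namespace {

// Restricted-neighbourhood-search state over one connected component.
// Cluster ids live in [0, n); empty ids are recycled through a sorted free set
// so that "open a new singleton cluster" is deterministic.
struct Rnsc {
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<std::unordered_set<int>> adjset;
  std::vector<int> deg;

  std::vector<int> assign;                 // vertex -> cluster id
  std::vector<int> csize;                  // cluster id -> size
  std::vector<std::vector<int>> members;   // cluster id -> member vertices
  std::set<int> freeIds;
  std::vector<int> dcur;                   // neighbours inside own cluster

  // tabu bookkeeping
  std::deque<int> tabuList;
  std::vector<int> tabuCount;
  int tabuTol, tabuLen;

  bool debug;
  double maxDebugDiff;

  Rnsc(const List& adjList, int tabuTol_, int tabuLen_, bool debug_)
      : tabuTol(tabuTol_), tabuLen(tabuLen_), debug(debug_), maxDebugDiff(0.0) {
    n = adjList.size();
    adj.resize(n);
    adjset.resize(n);
    deg.resize(n);
    for (int v = 0; v < n; ++v) {
      IntegerVector nb = adjList[v];
      adj[v] = std::vector<int>(nb.begin(), nb.end());
      adjset[v] = std::unordered_set<int>(nb.begin(), nb.end());
      deg[v] = adj[v].size();
    }
    assign.assign(n, -1);
    csize.assign(n, 0);
    members.assign(n, {});
    dcur.assign(n, 0);
    tabuCount.assign(n, 0);
    for (int c = 0; c < n; ++c) freeIds.insert(c);
  }

  void seedRandom() {
    int k0 = std::max(1, (int)std::floor(std::sqrt((double)n)));
    for (int v = 0; v < n; ++v) {
      int c = (int)std::floor(unif_rand() * k0);
      if (c >= k0) c = k0 - 1;
      placeInitial(v, c);
    }
    for (int v = 0; v < n; ++v) dcur[v] = countIn(v, assign[v]);
  }

  void placeInitial(int v, int c) {
    assign[v] = c;
    csize[c] += 1;
    members[c].push_back(v);
    freeIds.erase(c);
  }

  int countIn(int v, int c) const {
    int d = 0;
    for (int u : adj[v])
      if (assign[u] == c) ++d;
    return d;
  }

  // naive misplaced-connection count for one vertex
  inline int mis(int v) const {
    int d = dcur[v];
    return (deg[v] - d) + (csize[assign[v]] - 1 - d);
  }

  // |cluster(v) U neighbours(v)|
  inline int denom(int v) const {
    return csize[assign[v]] + deg[v] - dcur[v];
  }

  double naiveCostFull() const {
    double s = 0;
    for (int v = 0; v < n; ++v) s += mis(v);
    return s;
  }

  double scaledCostFull() const {
    double s = 0;
    for (int v = 0; v < n; ++v) s += (double)mis(v) / (double)denom(v);
    return s * ((double)n / 3.0);
  }

  // Delta of the naive cost when v moves to cluster b (b == -1: new cluster).
  double naiveDelta(int v, int b) const {
    int a = assign[v];
    int da = dcur[v];
    int db = (b < 0) ? 0 : countIn(v, b);
    int szb = (b < 0) ? 0 : csize[b];
    return 2.0 * (2 * da - 2 * db + szb - csize[a] + 1);
  }

  // Exact delta of the scaled cost for the same move; O(|A| + |B|).
  double scaledDelta(int v, int b) const {
    int a = assign[v];
    int da = dcur[v];
    int db = (b < 0) ? 0 : countIn(v, b);
    int sza = csize[a];
    int szb = (b < 0) ? 0 : csize[b];
    double d = 0;

    // v itself
    double before = (double)((deg[v] - da) + (sza - 1 - da)) /
                    (double)(sza + deg[v] - da);
    double after = (double)((deg[v] - db) + (szb - db)) /
                   (double)(szb + 1 + deg[v] - db);
    d += after - before;

    // members of the source cluster lose v
    for (int u : members[a]) {
      if (u == v) continue;
      int e = adjset[u].count(v) ? 1 : 0;
      int mu = (deg[u] - dcur[u]) + (sza - 1 - dcur[u]);
      int du = sza + deg[u] - dcur[u];
      int mu2 = mu + (e ? 1 : -1);
      int du2 = du + (e ? 0 : -1);
      d += (double)mu2 / (double)du2 - (double)mu / (double)du;
    }

    // members of the target cluster gain v
    if (b >= 0) {
      for (int u : members[b]) {
        int e = adjset[u].count(v) ? 1 : 0;
        int mu = (deg[u] - dcur[u]) + (szb - 1 - dcur[u]);
        int du = szb + deg[u] - dcur[u];
        int mu2 = mu + (e ? -1 : 1);
        int du2 = du + (e ? 0 : 1);
        d += (double)mu2 / (double)du2 - (double)mu / (double)du;
      }
    }
    return d * ((double)n / 3.0);
  }

  // Apply the move; returns the actual cluster id used for b (resolving -1).
  int applyMove(int v, int b) {
    int a = assign[v];
    if (b < 0) {
      b = *freeIds.begin();
      freeIds.erase(freeIds.begin());
    }
    // remove from a
    csize[a] -= 1;
    auto& ma = members[a];
    ma.erase(std::find(ma.begin(), ma.end(), v));
    if (csize[a] == 0) freeIds.insert(a);
    // insert into b
    assign[v] = b;
    csize[b] += 1;
    members[b].push_back(v);
    freeIds.erase(b);
    // refresh same-cluster neighbour counts
    for (int u : adj[v]) {
      if (assign[u] == a) dcur[u] -= 1;
      else if (assign[u] == b) dcur[u] += 1;
    }
    dcur[v] = countIn(v, b);
    return b;
  }

  void pushTabu(int v) {
    tabuList.push_back(v);
    tabuCount[v] += 1;
    while ((int)tabuList.size() > tabuLen) {
      tabuCount[tabuList.front()] -= 1;
      tabuList.pop_front();
    }
  }

  inline bool isTabu(int v) const { return tabuCount[v] >= tabuTol; }

  // Candidate target clusters of v: clusters of its neighbours (ascending id)
  // plus -1 for a fresh singleton (skipped when v is already a singleton).
  void candidates(int v, std::vector<int>& out) const {
    out.clear();
    std::set<int> cs;
    for (int u : adj[v]) {
      int c = assign[u];
      if (c != assign[v]) cs.insert(c);
    }
    for (int c : cs) out.push_back(c);
    if (csize[assign[v]] > 1) out.push_back(-1);
  }

  // One phase of the search (scaled == false: naive cost).
  // Returns the best assignment found; best-cost trace appended to `trace`.
  std::vector<int> phase(bool scaled, int stopTol, int divFreq, int shufLen,
                         int maxSteps, std::vector<double>& trace) {
    double cost = scaled ? scaledCostFull() : naiveCostFull();
    double bestCost = cost;
    std::vector<int> bestAssign = assign;
    trace.push_back(bestCost);
    int sinceBest = 0, step = 0;
    std::vector<int> cand;

    while (sinceBest < stopTol && step < maxSteps) {
      ++step;
      if (divFreq > 0 && step % divFreq == 0) {
        // shuffling diversification: random vertices to random clusters
        for (int i = 0; i < shufLen; ++i) {
          int v = (int)std::floor(unif_rand() * n);
          if (v >= n) v = n - 1;
          candidates(v, cand);
          if (cand.empty()) continue;
          int pick = (int)std::floor(unif_rand() * cand.size());
          if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
          double delta = scaled ? scaledDelta(v, cand[pick])
                                : naiveDelta(v, cand[pick]);
          applyMove(v, cand[pick]);
          pushTabu(v);
          cost += delta;
        }
      } else {
        int bv = -1, bc = 0;
        double bd = 0;
        bool found = false;
        for (int pass = 0; pass < 2 && !found; ++pass) {
          // pass 0 honours the tabu list; pass 1 ignores it (fallback when
          // every vertex with a move is tabu)
          for (int v = 0; v < n; ++v) {
            if (pass == 0 && isTabu(v)) continue;
            candidates(v, cand);
            for (int c : cand) {
              double d = scaled ? scaledDelta(v, c) : naiveDelta(v, c);
              if (!found || d < bd - 1e-12) {
                found = true;
                bd = d;
                bv = v;
                bc = c;
              }
            }
          }
        }
        if (!found) break;  // no moves at all (e.g. single vertex)
        applyMove(bv, bc);
        pushTabu(bv);
        cost += bd;
      }
      if (debug) {
        double full = scaled ? scaledCostFull() : naiveCostFull();
        double diff = std::fabs(full - cost);
        if (diff > maxDebugDiff) maxDebugDiff = diff;
        cost = full;  // keep drift out of long debug runs
      }
      if (cost < bestCost - 1e-9) {
        bestCost = cost;
        bestAssign = assign;
        sinceBest = 0;
        trace.push_back(bestCost);
      } else {
        ++sinceBest;
      }
    }
    return bestAssign;
  }

  void loadAssignment(const std::vector<int>& a) {
    csize.assign(n, 0);
    members.assign(n, {});
    freeIds.clear();
    for (int c = 0; c < n; ++c) freeIds.insert(c);
    assign = a;
    for (int v = 0; v < n; ++v) {
      csize[assign[v]] += 1;
      members[assign[v]].push_back(v);
      freeIds.erase(assign[v]);
    }
    for (int v = 0; v < n; ++v) dcur[v] = countIn(v, assign[v]);
  }
};

}  // namespace

// Two-phase RNSC search over one connected component. `adjList` holds 0-based
// neighbour vectors; randomness is drawn from R's RNG (set.seed upstream).
// [[Rcpp::export(name = ".rnsc_search_cpp")]]
List rnsc_search_cpp(List adjList, int tabu_tolerance, int tabu_length,
                     int naive_stopping_tolerance,
                     int scaled_stopping_tolerance,
                     int diversification_frequency,
                     int shuffling_diversification_length, int max_steps,
                     bool debug) {
  Rnsc st(adjList, tabu_tolerance, tabu_length, debug);
  st.seedRandom();

  std::vector<double> naiveTrace, scaledTrace;
  std::vector<int> bestNaive =
      st.phase(false, naive_stopping_tolerance, diversification_frequency,
               shuffling_diversification_length, max_steps, naiveTrace);

  st.loadAssignment(bestNaive);
  st.tabuList.clear();
  std::fill(st.tabuCount.begin(), st.tabuCount.end(), 0);
  std::vector<int> bestScaled =
      st.phase(true, scaled_stopping_tolerance, diversification_frequency,
               shuffling_diversification_length, max_steps, scaledTrace);

  st.loadAssignment(bestScaled);

  // renumber clusters 0..k-1 in order of first appearance by vertex index
  std::vector<int> remap(st.n, -1);
  int next = 0;
  IntegerVector out(st.n);
  for (int v = 0; v < st.n; ++v) {
    int c = st.assign[v];
    if (remap[c] < 0) remap[c] = next++;
    out[v] = remap[c];
  }

  return List::create(
      _["assignment"] = out, _["n_clusters"] = next,
      _["naive_cost"] = st.naiveCostFull(),
      _["scaled_cost"] = st.scaledCostFull(),
      _["naive_trace"] = NumericVector(naiveTrace.begin(), naiveTrace.end()),
      _["scaled_trace"] = NumericVector(scaledTrace.begin(), scaledTrace.end()),
      _["debug_max_diff"] = st.maxDebugDiff);
}
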