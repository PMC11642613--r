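// Kinetic Monte Carlo engine for the interacting-cell-system lattice model.
//
// Four cell types live on an n_rows x n_cols chamber grid with a hard
// per-chamber occupancy cap: melanoma (M), activated CD8+ T (T), exhausted
// CD8+ T (E), tumor-associated macrophages (A). Events:
//   - melanoma proliferation, per melanoma cell
//   - lysis of melanoma by activated T, per contact pair (same chamber or
//     contact-neighborhood chamber)
//   - exhaustion of activated T by melanoma, per contact pair (rate bC)
//   - exhaustion of activated T by TAM, per same-chamber pair (rate bM)
//   - activated-T proliferation and slide-wide recruitment, with rates
//     linear in L = melanoma cells lysed in the previous feedback window
//   - exhausted-T death, per cell
//   - diffusive hops of T, E and TAM to hop-neighborhood chambers
// Blocked proliferation/hop/recruitment attempts are null events (time
// advances, no state change). Boundaries are reflecting. Waiting times are
// exponential in the total rate; rates are piecewise constant between
// feedback-window boundaries, where the clock is resampled (valid by
// memorylessness of the exponential).
//
// Pair totals are maintained incrementally with per-chamber neighborhood
// sums, and chambers are sampled proportionally to integer weights with
// Fenwick (binary indexed) trees, so one event costs O(k log n) with k the
// neighborhood size. All randomness comes from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Fenwick {
  int n;                    // number of leaves
  int sz;                   // power of two >= n
  std::vector<long long> t; // 1-based tree
  long long total;

  void init(int n_) {
    n = n_;
    sz = 1;
    while (sz < n) sz <<= 1;
    t.assign(n + 1, 0LL);
    total = 0;
  }
  void add(int i, long long d) { // 0-based leaf index
    if (d == 0) return;
    total += d;
    for (int j = i + 1; j <= n; j += j & (-j)) t[j] += d;
  }
  // sample leaf with probability weight/total; u in [0,1)
  int sample(double u) const {
    double target = u * (double)total;
    int pos = 0;
    long long acc = 0;
    for (int step = sz; step > 0; step >>= 1) {
      int next = pos + step;
      if (next <= n) {
        double val = (double)(acc + t[next]);
        if (val <= target) {
          pos = next;
          acc += t[next];
        }
      }
    }
    // pos is the count of leaves with cumulative weight <= target
    if (pos >= n) pos = n - 1;
    return pos;
  }
};

struct Engine {
  int nr, nc, n, cap;
  std::vector<long long> M, T, E, A, occ;
  std::vector<long long> Mnb, Tnb; // contact-neighborhood sums (incl. self)
  Fenwick fM, fT, fE, fA, fLys, fExh, fTm;
  long long totM, totT, totE, totA, S_pair, S_tm;
  std::vector<int> cOff, hOff; // neighbor index offsets packaged as dr*1000+dc
  // we store neighbor deltas as (dr, dc) pairs
  std::vector<std::pair<int,int>> cNb, hNb; // contact (incl self), hop (excl self)

  int idx(int r, int c) const { return r * nc + c; }

  void setNeighborhoods(bool contact_moore, bool hop_moore) {
    cNb.clear(); hNb.clear();
    cNb.push_back({0, 0});
    const int m8[8][2] = {{-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}};
    const int v4[4][2] = {{-1,0},{1,0},{0,-1},{0,1}};
    if (contact_moore) for (auto &d : m8) cNb.push_back({d[0], d[1]});
    else for (auto &d : v4) cNb.push_back({d[0], d[1]});
    if (hop_moore) for (auto &d : m8) hNb.push_back({d[0], d[1]});
    else for (auto &d : v4) hNb.push_back({d[0], d[1]});
  }

  void initState(const IntegerMatrix &M0, const IntegerMatrix &T0,
                 const IntegerMatrix &E0, const IntegerMatrix &A0) {
    nr = M0.nrow(); nc = M0.ncol(); n = nr * nc;
    M.assign(n, 0); T.assign(n, 0); E.assign(n, 0); A.assign(n, 0);
    occ.assign(n, 0); Mnb.assign(n, 0); Tnb.assign(n, 0);
    totM = totT = totE = totA = 0;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        int i = idx(r, c);
        M[i] = M0(r, c); T[i] = T0(r, c); E[i] = E0(r, c); A[i] = A0(r, c);
        occ[i] = M[i] + T[i] + E[i] + A[i];
        totM += M[i]; totT += T[i]; totE += E[i]; totA += A[i];
      }
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        int i = idx(r, c);
        long long ms = 0, ts = 0;
        for (auto &d : cNb) {
          int rr = r + d.first, cc = c + d.second;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          ms += M[idx(rr, cc)];
          ts += T[idx(rr, cc)];
        }
        Mnb[i] = ms; Tnb[i] = ts;
      }
    fM.init(n); fT.init(n); fE.init(n); fA.init(n);
    fLys.init(n); fExh.init(n); fTm.init(n);
    S_pair = 0; S_tm = 0;
    for (int i = 0; i < n; ++i) {
      fM.add(i, M[i]); fT.add(i, T[i]); fE.add(i, E[i]); fA.add(i, A[i]);
      fLys.add(i, M[i] * Tnb[i]);
      fExh.add(i, T[i] * Mnb[i]);
      fTm.add(i, T[i] * A[i]);
      S_pair += M[i] * Tnb[i];
      S_tm += T[i] * A[i];
    }
  }

  void changeM(int i, long long d) {
    int r = i / nc, c = i % nc;
    M[i] += d; occ[i] += d; totM += d;
    fM.add(i, d);
    fLys.add(i, d * Tnb[i]);
    S_pair += d * Tnb[i];
    for (auto &dd : cNb) {
      int rr = r + dd.first, cc = c + dd.second;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc);
      Mnb[j] += d;
      fExh.add(j, d * T[j]);
    }
  }
  void changeT(int i, long long d) {
    int r = i / nc, c = i % nc;
    T[i] += d; occ[i] += d; totT += d;
    fT.add(i, d);
    fExh.add(i, d * Mnb[i]);
    fTm.add(i, d * A[i]);
    S_pair += d * Mnb[i];
    S_tm += d * A[i];
    for (auto &dd : cNb) {
      int rr = r + dd.first, cc = c + dd.second;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc);
      Tnb[j] += d;
      fLys.add(j, d * M[j]);
    }
  }
  void changeE(int i, long long d) {
    E[i] += d; occ[i] += d; totE += d;
    fE.add(i, d);
  }
  void changeA(int i, long long d) {
    A[i] += d; occ[i] += d; totA += d;
    fA.add(i, d);
    fTm.add(i, d * T[i]);
    S_tm += d * T[i];
  }

  // place a daughter of the given type: same chamber if room, else a
  // uniformly chosen hop-neighborhood chamber with room, else null
  template <typename F>
  void placeDaughter(int i, F change) {
    if (occ[i] < cap) { change(i, 1LL); return; }
    int r = i / nc, c = i % nc;
    int options[8]; int nopt = 0;
    for (auto &dd : hNb) {
      int rr = r + dd.first, cc = c + dd.second;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc);
      if (occ[j] < cap) options[nopt++] = j;
    }
    if (nopt == 0) return; // null event
    int j = options[(int)(unif_rand() * nopt) % nopt];
    change(j, 1LL);
  }

  // hop one cell of a type from chamber i; null if blocked
  template <typename F>
  void hop(int i, F change) {
    int r = i / nc, c = i % nc;
    int k = (int)(unif_rand() * hNb.size()) % hNb.size();
    int rr = r + hNb[k].first, cc = c + hNb[k].second;
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) return;
    int j = idx(rr, cc);
    if (occ[j] >= cap) return;
    change(i, -1LL);
    change(j, 1LL);
  }
};

} // namespace

// [[Rcpp::export]]
List kmc_run(IntegerMatrix M0, IntegerMatrix T0, IntegerMatrix E0,
             IntegerMatrix A0, int cap, List params, double t_end,
             double record_every, bool contact_moore, bool hop_moore,
             NumericVector snapshot_times) {
  const double r_mel = params["r_prolif_mel"];
  const double lrate = params["l"];
  const double bC = params["bC"];
  const double bM = params["bM"];
  const double r_dex = params["r_death_ex"];
  const double r_hT = params["r_hop_T"];
  const double r_hM = params["r_hop_M"];
  const double r_T0 = params["r_prolif_T0"];
  const double k_p = params["k_prolif"];
  const double r_rec0 = params["r_recruit0"];
  const double k_rec = params["k_recruit"];
  const double dt_fb = params["dt_feedback"];

  Engine eng;
  eng.cap = cap;
  eng.setNeighborhoods(contact_moore, hop_moore);
  eng.initState(M0, T0, E0, A0);
  const int n = eng.n;

  // recording grid 0, record_every, ..., t_end (t_end always included)
  std::vector<double> rec_times;
  for (double tt = 0.0; tt < t_end - 1e-9; tt += record_every)
    rec_times.push_back(tt);
  rec_times.push_back(t_end);
  const int n_rec = rec_times.size();
  IntegerVector recM(n_rec), recT(n_rec), recE(n_rec), recA(n_rec);
  NumericVector recTime(n_rec);
  int rec_i = 0;

  std::vector<double> snaps(snapshot_times.begin(), snapshot_times.end());
  std::sort(snaps.begin(), snaps.end());
  List snap_out(snaps.size());
  size_t snap_i = 0;

  auto record = [&](int k) {
    recTime[k] = rec_times[k];
    recM[k] = (int)eng.totM; recT[k] = (int)eng.totT;
    recE[k] = (int)eng.totE; recA[k] = (int)eng.totA;
  };
  auto takeSnapshot = [&](size_t k) {
    IntegerMatrix sm(eng.nr, eng.nc), st(eng.nr, eng.nc),
        se(eng.nr, eng.nc), sa(eng.nr, eng.nc);
    for (int r = 0; r < eng.nr; ++r)
      for (int c = 0; c < eng.nc; ++c) {
        int i = eng.idx(r, c);
        sm(r, c) = (int)eng.M[i]; st(r, c) = (int)eng.T[i];
        se(r, c) = (int)eng.E[i]; sa(r, c) = (int)eng.A[i];
      }
    snap_out[k] = List::create(
        _["time_h"] = snaps[k], _["melanoma"] = sm, _["t_active"] = st,
        _["t_exhausted"] = se, _["tam"] = sa);
  };
  // flush record/snapshot times strictly below tt (carry last state forward)
  auto flushBefore = [&](double tt) {
    while (rec_i < n_rec && rec_times[rec_i] < tt) record(rec_i++);
    while (snap_i < snaps.size() && snaps[snap_i] < tt) takeSnapshot(snap_i++);
  };

  double t = 0.0;
  long long lysed_cur = 0, lysed_prev = 0, total_lysed = 0;
  double next_window = dt_fb;
  long long n_events = 0;

  while (t < t_end) {
    double L = (double)lysed_prev;
    double rate[9];
    rate[0] = r_mel * (double)eng.totM;
    rate[1] = lrate * (double)eng.S_pair;
    rate[2] = bC * (double)eng.S_pair;
    rate[3] = bM * (double)eng.S_tm;
    rate[4] = (r_T0 + k_p * L) * (double)eng.totT;
    rate[5] = r_rec0 + k_rec * L; // slide-wide recruitment, always enabled
    rate[6] = r_dex * (double)eng.totE;
    rate[7] = r_hT * (double)(eng.totT + eng.totE);
    rate[8] = r_hM * (double)eng.totA;
    double Rtot = 0.0;
    for (int k = 0; k < 9; ++k) Rtot += rate[k];

    if (Rtot <= 0.0) {
      // no events possible until the next feedback-window boundary (which
      // can only lower rates further) -> counts stay constant to t_end
      if (next_window < t_end) {
        t = next_window;
        lysed_prev = lysed_cur;
        lysed_cur = 0;
        next_window += dt_fb;
        continue;
      }
      break;
    }

    double u = unif_rand();
    if (u <= 0.0) u = 1e-300;
    double dt = -std::log(u) / Rtot;
    double t_next = t + dt;

    if (t_next >= next_window && next_window < t_end) {
      // cross the feedback boundary without firing; resample with new L
      flushBefore(next_window);
      t = next_window;
      lysed_prev = lysed_cur;
      lysed_cur = 0;
      next_window += dt_fb;
      continue;
    }
    if (t_next > t_end) {
      t = t_end;
      break;
    }

    flushBefore(t_next);
    t = t_next;
    ++n_events;

    double v = unif_rand() * Rtot;
    int ev = 0;
    double acc = rate[0];
    while (ev < 8 && v > acc) acc += rate[++ev];

    switch (ev) {
    case 0: { // melanoma proliferation
      int i = eng.fM.sample(unif_rand());
      eng.placeDaughter(i, [&](int j, long long d) { eng.changeM(j, d); });
      break;
    }
    case 1: { // lysis: remove a melanoma chosen prop. to M[i]*Tnb[i]
      int i = eng.fLys.sample(unif_rand());
      eng.changeM(i, -1);
      ++lysed_cur;
      ++total_lysed;
      break;
    }
    case 2: { // exhaustion by melanoma: T chosen prop. to T[i]*Mnb[i]
      int i = eng.fExh.sample(unif_rand());
      eng.changeT(i, -1);
      eng.changeE(i, 1);
      break;
    }
    case 3: { // exhaustion by TAM, same chamber
      int i = eng.fTm.sample(unif_rand());
      eng.changeT(i, -1);
      eng.changeE(i, 1);
      break;
    }
    case 4: { // activated-T proliferation
      int i = eng.fT.sample(unif_rand());
      eng.placeDaughter(i, [&](int j, long long d) { eng.changeT(j, d); });
      break;
    }
    case 5: { // recruitment into a uniformly random chamber
      int i = (int)(unif_rand() * n) % n;
      if (eng.occ[i] < cap) eng.changeT(i, 1);
      break;
    }
    case 6: { // exhausted-T death
      int i = eng.fE.sample(unif_rand());
      eng.changeE(i, -1);
      break;
    }
    case 7: { // hop of a CD8+ T cell (activated or exhausted)
      double w = unif_rand() * (double)(eng.totT + eng.totE);
      if (w < (double)eng.totT) {
        int i = eng.fT.sample(unif_rand());
        eng.hop(i, [&](int j, long long d) { eng.changeT(j, d); });
      } else {
        int i = eng.fE.sample(unif_rand());
        eng.hop(i, [&](int j, long long d) { eng.changeE(j, d); });
      }
      break;
    }
    case 8: { // TAM hop
      int i = eng.fA.sample(unif_rand());
      eng.hop(i, [&](int j, long long d) { eng.changeA(j, d); });
      break;
    }
    }
  }

  // flush remaining recording/snapshot times with the final state
  flushBefore(t_end + 1.0);
  while (rec_i < n_rec) record(rec_i++);
  while (snap_i < snaps.size()) takeSnapshot(snap_i++);

  return List::create(
      _["time_h"] = recTime, _["n_melanoma"] = recM, _["n_t_active"] = recT,
      _["n_t_exhausted"] = recE, _["n_tam"] = recA,
      _["snapshots"] = snap_out, _["n_events"] = (double)n_events,
      _["total_lysed"] = (double)total_lysed);
}
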