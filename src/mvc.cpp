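#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <chrono>
using namespace Rcpp;

static const int INF = 1 << 29;
static long long g_nodes, g_limit;
static bool g_abort;
static std::chrono::steady_clock::time_point g_t0;
static double g_tlimit;

struct Sub {
  int n;
  std::vector<std::vector<int>> adj; // local indices
  std::vector<int> orig;             // local -> caller id
};

// result: size (INF if pruned/aborted) + cover in orig ids
struct Res { int size; std::vector<int> cover; };

static Res solveRec(Sub g, int ub);

// build induced subgraph on alive vertices listed in vs (local ids of parent)
static Sub induced(const std::vector<std::vector<int>>& adj,
                   const std::vector<char>& alive,
                   const std::vector<int>& orig,
                   const std::vector<int>& vs) {
  Sub s; s.n = vs.size();
  std::vector<int> loc(adj.size(), -1);
  for (int i = 0; i < (int)vs.size(); ++i) loc[vs[i]] = i;
  s.adj.assign(s.n, {});
  s.orig.resize(s.n);
  for (int i = 0; i < (int)vs.size(); ++i) {
    s.orig[i] = orig[vs[i]];
    for (int u : adj[vs[i]])
      if (alive[u] && loc[u] >= 0) s.adj[i].push_back(loc[u]);
  }
  return s;
}

static Res solveRec(Sub g, int ub) {
  if (g_abort || ++g_nodes > g_limit) { g_abort = true; return {INF, {}}; }
  if ((g_nodes & 2047) == 0 &&
      std::chrono::duration<double>(std::chrono::steady_clock::now() - g_t0).count() > g_tlimit) {
    g_abort = true; return {INF, {}};
  }
  int n = g.n;
  std::vector<char> alive(n, 1);
  std::vector<int> deg(n);
  for (int v = 0; v < n; ++v) deg[v] = g.adj[v].size();

  std::vector<int> cover;               // orig ids fixed by reductions
  struct Fold { int v, u, w; };          // orig... store LOCAL ids, resolve at end
  std::vector<Fold> folds;
  int foldCredit = 0;

  auto rm = [&](int v) { alive[v] = 0; for (int u : g.adj[v]) if (alive[u]) deg[u]--; };
  auto isAdj = [&](int a, int b) {
    for (int x : g.adj[a]) if (x == b && alive[x]) return true;
    return false;
  };

  bool changed = true;
  while (changed) {
    changed = false;
    for (int v = 0; v < n; ++v) {
      if (!alive[v]) continue;
      if (deg[v] == 0) { rm(v); continue; }
      if (deg[v] == 1) {
        int u = -1;
        for (int w : g.adj[v]) if (alive[w]) { u = w; break; }
        // isolated edge: either endpoint is optimal; take the
        // lower-indexed one so ties break lexicographically
        int pick = (deg[u] == 1 && v < u) ? v : u;
        cover.push_back(pick); rm(u); rm(v); changed = true;
      } else if (deg[v] == 2) {
        int u = -1, w = -1;
        for (int x : g.adj[v]) if (alive[x]) { if (u < 0) u = x; else { w = x; break; } }
        if (isAdj(u, w)) {            // triangle: u,w into cover
          cover.push_back(u); cover.push_back(w);
          rm(u); rm(w); rm(v); changed = true;
        } else {                       // fold v into u
          // u absorbs N(w)\{v}; remove v, w
          for (int x : g.adj[w]) {
            if (alive[x] && x != v && x != u && !isAdj(u, x)) {
              g.adj[u].push_back(x); g.adj[x].push_back(u);
              deg[u]++; deg[x]++;
            }
          }
          rm(w); rm(v);
          folds.push_back({v, u, w});
          foldCredit++; changed = true;
        }
      }
    }
    int nAlive = 0;
    for (int v = 0; v < n; ++v) if (alive[v]) nAlive++;
    if (!changed && nAlive >= 120) {
      // unconfined-vertex rule: an unconfined vertex belongs to some minimum
      // cover; worth its cost only on large residual graphs
      std::vector<char> inS(n, 0), inNS(n, 0);
      std::vector<int> touched;
      for (int v = 0; v < n; ++v) {
        if (!alive[v] || deg[v] < 2) continue;
        for (int t : touched) { inS[t] = 0; inNS[t] = 0; }
        touched.clear();
        std::vector<int> S{v};
        inS[v] = 1; inNS[v] = 1; touched.push_back(v);
        for (int u : g.adj[v]) if (alive[u]) { inNS[u] = 1; touched.push_back(u); }
        bool unconfined = false;
        for (;;) {
          int pick = -1, pickExtra = -1, extraVert = -1;
          for (int s : S) {
            for (int u : g.adj[s]) {
              if (!alive[u] || inS[u]) continue;
              int common = 0;
              for (int x : g.adj[u]) if (alive[x] && inS[x]) common++;
              if (common != 1) continue;
              int extra = 0, ev = -1;
              for (int x : g.adj[u]) if (alive[x] && !inNS[x]) { extra++; ev = x; }
              if (pick == -1 || extra < pickExtra) { pick = u; pickExtra = extra; extraVert = ev; }
              if (pickExtra == 0) break;
            }
            if (pick != -1 && pickExtra == 0) break;
          }
          if (pick == -1) break;
          if (pickExtra == 0) { unconfined = true; break; }
          if (pickExtra == 1) {
            S.push_back(extraVert);
            inS[extraVert] = 1; inNS[extraVert] = 1; touched.push_back(extraVert);
            for (int x : g.adj[extraVert]) if (alive[x]) { inNS[x] = 1; touched.push_back(x); }
            continue;
          }
          break;
        }
        if (unconfined) { cover.push_back(v); rm(v); changed = true; }
      }
    }
  }

  int base = (int)cover.size() + foldCredit;
  if (base >= ub) return {INF, {}};

  // components of alive graph
  std::vector<int> compId(n, -1);
  std::vector<std::vector<int>> comps;
  for (int v = 0; v < n; ++v) {
    if (!alive[v] || compId[v] >= 0 || deg[v] == 0) continue;
    std::vector<int> q{v}, comp;
    compId[v] = comps.size();
    while (!q.empty()) {
      int x = q.back(); q.pop_back(); comp.push_back(x);
      for (int u : g.adj[x])
        if (alive[u] && compId[u] < 0) { compId[u] = comps.size(); q.push_back(u); }
    }
    std::sort(comp.begin(), comp.end());
    comps.push_back(comp);
  }
  std::sort(comps.begin(), comps.end(),
            [](const std::vector<int>& a, const std::vector<int>& b) {
              return a.size() < b.size(); });

  // matching lower bound per component (greedy + augmenting paths, no blossoms)
  std::vector<int> lb(comps.size(), 0);
  {
    std::vector<int> mate(n, -1);
    for (size_t c = 0; c < comps.size(); ++c) {
      for (int v : comps[c]) {
        if (mate[v] >= 0) continue;
        for (int u : g.adj[v])
          if (alive[u] && mate[u] < 0) { mate[v] = u; mate[u] = v; break; }
      }
      // augmenting passes (bipartite-style alternating BFS; misses blossoms, still a valid LB)
      bool improved = true;
      int guard = 0;
      while (improved && guard++ < 5) {
        improved = false;
        for (int v : comps[c]) {
          if (mate[v] >= 0) continue;
          // BFS over alternating paths from v
          std::vector<int> par(n, -2);
          std::vector<int> q{v}; par[v] = -1;
          int endv = -1;
          for (size_t qi = 0; qi < q.size() && endv < 0; ++qi) {
            int x = q[qi];
            for (int u : g.adj[x]) {
              if (!alive[u] || par[u] != -2) continue;
              par[u] = x;
              if (mate[u] < 0) { endv = u; break; }
              if (par[mate[u]] == -2) { par[mate[u]] = u; q.push_back(mate[u]); }
            }
          }
          if (endv >= 0) {
            int u = endv;
            while (u != -1) {
              int x = par[u];
              int nx = (x == -1) ? -1 : par[x];
              mate[u] = x; mate[x] = u;
              u = nx;
            }
            improved = true;
          }
        }
      }
      for (int v : comps[c]) if (mate[v] >= 0) lb[c]++;
      lb[c] /= 2;
    }
  }
  int lbSum = std::accumulate(lb.begin(), lb.end(), 0);
  if (base + lbSum >= ub) return {INF, {}};

  // local cover in LOCAL ids for unfolding, seed from reductions (convert later).
  // We keep everything in local ids until unfolding, then map to orig.
  std::vector<int> chosenLocal = cover; // reduction picks (local ids)

  int total = base;
  bool infeasible = false;
  std::vector<int> compPick; // local ids from components

  for (size_t c = 0; c < comps.size() && !infeasible; ++c) {
    const std::vector<int>& comp = comps[c];
    int budget = ub - total - (lbSum - lb[c]); // max allowed for this comp (exclusive)
    if (budget <= lb[c]) { infeasible = true; break; }

    // path/cycle closed form
    int maxd = 0;
    for (int v : comp) maxd = std::max(maxd, deg[v]);
    if (maxd <= 2) {
      // walk
      std::vector<char> seen(comp.size(), 0);
      std::vector<int> loc(n, -1);
      for (size_t i = 0; i < comp.size(); ++i) loc[comp[i]] = i;
      int start = -1;
      for (int v : comp) if (deg[v] == 1) { start = v; break; }
      bool isCycle = (start == -1);
      if (isCycle) start = comp[0];
      std::vector<int> order;
      int prev = -1, cur = start;
      while (cur != -1 && order.size() < comp.size()) {
        order.push_back(cur);
        int nxt = -1;
        for (int u : g.adj[cur]) if (alive[u] && u != prev) { nxt = u; break; }
        if (nxt == start) break;
        prev = cur; cur = nxt;
      }
      int L = order.size(), got = 0;
      for (int i = 1; i < L; i += 2) { compPick.push_back(order[i]); got++; }
      if (isCycle && L % 2 == 1) { compPick.push_back(order[L-1]); got++; }
      if (got >= budget) { infeasible = true; break; }
      total += got;
      lbSum -= lb[c];
      continue;
    }

    // branch on max-degree vertex (smallest id tie-break)
    int bv = comp[0], bd = -1;
    for (int v : comp) if (deg[v] > bd) { bd = deg[v]; bv = v; }

    auto branch = [&](const std::vector<int>& intoCover) -> Res {
      std::vector<char> a2(n, 0);
      for (int v : comp) a2[v] = 1;
      for (int v : intoCover) a2[v] = 0;
      std::vector<int> vs;
      for (int v : comp) if (a2[v]) vs.push_back(v);
      // identity orig map (local ids)
      std::vector<int> ident(n); std::iota(ident.begin(), ident.end(), 0);
      Sub s = induced(g.adj, a2, ident, vs);
      int subUb = budget - (int)intoCover.size();
      if (subUb <= 0) return {INF, {}};
      Res r = solveRec(std::move(s), subUb);
      if (r.size >= INF) return {INF, {}};
      r.size += (int)intoCover.size();
      for (int v : intoCover) r.cover.push_back(v);
      return r;
    };
    Res rA = branch({bv});
    if (rA.size < INF) budget = std::min(budget, rA.size); // tighten
    std::vector<int> nb;
    for (int u : g.adj[bv]) if (alive[u]) nb.push_back(u);
    Res rB = branch(nb);
    Res* win = nullptr;
    if (rA.size <= rB.size) win = &rA; else win = &rB;
    if (win->size >= INF) { infeasible = true; break; }
    total += win->size;
    for (int v : win->cover) compPick.push_back(v);
    lbSum -= lb[c];
  }

  if (infeasible || total >= ub) return {INF, {}};

  // assemble local solution and unfold
  std::vector<char> sel(n, 0);
  for (int v : chosenLocal) sel[v] = 1;
  for (int v : compPick) sel[v] = 1;
  for (int i = (int)folds.size() - 1; i >= 0; --i) {
    const Fold& f = folds[i];
    if (sel[f.u]) sel[f.w] = 1; else sel[f.v] = 1;
  }
  Res out; out.size = 0;
  for (int v = 0; v < n; ++v) if (sel[v]) { out.size++; out.cover.push_back(g.orig[v]); }
  return out;
}

// [[Rcpp::export]]
List mvc_solve_cpp(IntegerMatrix edges, int n, double nodeLimit, double timeLimit) {
  Sub g; g.n = n; g.adj.assign(n, {});
  g.orig.resize(n); std::iota(g.orig.begin(), g.orig.end(), 0);
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i,0), b = edges(i,1);
    g.adj[a].push_back(b); g.adj[b].push_back(a);
  }
  for (int v = 0; v < n; ++v) std::sort(g.adj[v].begin(), g.adj[v].end());
  std::vector<char> hasEdge(n, 0);
  for (int v = 0; v < n; ++v) if (!g.adj[v].empty()) hasEdge[v] = 1;
  g_nodes = 0; g_limit = (long long)nodeLimit; g_abort = false;
  g_t0 = std::chrono::steady_clock::now(); g_tlimit = timeLimit;
  Res r = solveRec(std::move(g), n + 1);
  if (r.size >= INF) {
    // aborted before any complete solution: fall back to the trivial
    // incumbent (all endpoints of edges); callers flag non-optimality
    r.cover.clear();
    for (int v = 0; v < n; ++v) if (hasEdge[v]) r.cover.push_back(v);
    r.size = r.cover.size();
  }
  return List::create(_["size"] = r.size, _["cover"] = IntegerVector(r.cover.begin(), r.cover.end()),
                      _["nodes"] = (double)g_nodes, _["optimal"] = !g_abort);
}
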