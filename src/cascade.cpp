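#include "cascade.h"
#include <cmath>
#include <algorithm>

void resolve_cascade_core(std::vector<double>& V,
                          const std::vector<char>& isI,
                          const int* ptr, const int* rcv,
                          const double* wf, const double* ws,
                          const std::function<bool(int)>& blocked,
                          const std::vector<int>& initiators,
                          const CascadeParams& P,
                          bool skipLR, const char* isLR,
                          const std::function<void(int)>& onTouch,
                          std::vector<int>& firedOrder,
                          std::vector<double>& slowPend,
                          CascadeWork& W)
{
    const int n = (int)V.size();
    W.ensure(n);
    W.touchedList.clear();
    std::vector<char> fired(n, 0);

    auto deliver = [&](int s) {
        const char senderI = isI[s];
        for (int e = ptr[s]; e < ptr[s + 1]; ++e) {
            if (skipLR && isLR && isLR[e]) continue;
            const int r = rcv[e];
            if (fired[r] || blocked(r)) continue;
            if (!W.touched[r]) {
                if (onTouch) onTouch(r);
                W.touched[r] = 1;
                W.touchedList.push_back(r);
            }
            if (senderI) W.b[r] += wf[e]; else W.a[r] += wf[e];
            if (ws) slowPend[r] += ws[e];
        }
    };

    for (int i : initiators) {
        if (fired[i]) continue;
        fired[i] = 1;
        firedOrder.push_back(i);
        deliver(i);
    }

    // event loop: earliest within-instant crossing = largest s* in (0, 1]
    for (;;) {
        double bestS = -1.0; int bestI = -1;
        for (int i : W.touchedList) {
            if (fired[i]) continue;
            const double tot = W.a[i] + W.b[i];
            if (tot <= 0.0) continue;
            if (V[i] >= P.VT) { bestI = i; bestS = 1.0; break; }
            const double Vs = (W.a[i] * P.VE + W.b[i] * P.VI) / tot;
            if (Vs <= P.VT) continue;
            const double c = tot / P.tauV;
            const double s = 1.0 + std::log((P.VT - Vs) / (V[i] - Vs)) / c;
            if (s <= 0.0) continue;
            if (s > bestS) { bestS = s; bestI = i; }
        }
        if (bestI < 0) break;

        if (bestS < 1.0) {
            for (int i : W.touchedList) {
                if (fired[i]) continue;
                const double tot = W.a[i] + W.b[i];
                if (tot <= 0.0) continue;
                const double Vs = (W.a[i] * P.VE + W.b[i] * P.VI) / tot;
                const double c = tot / P.tauV;
                V[i] = Vs + (V[i] - Vs) * std::exp(c * (bestS - 1.0));
                W.a[i] *= bestS; W.b[i] *= bestS;
            }
        }
        V[bestI] = P.VT;
        fired[bestI] = 1;
        firedOrder.push_back(bestI);
        deliver(bestI);
    }

    // deliver the remaining areas in full (s -> 0)
    for (int i : W.touchedList) {
        if (!fired[i]) {
            const double tot = W.a[i] + W.b[i];
            if (tot > 0.0) {
                const double Vs = (W.a[i] * P.VE + W.b[i] * P.VI) / tot;
                const double c = tot / P.tauV;
                V[i] = Vs + (V[i] - Vs) * std::exp(-c);
            }
        }
        W.a[i] = 0.0; W.b[i] = 0.0; W.touched[i] = 0;
    }
    for (int i : firedOrder) {
        V[i] = P.Vreset;
        if (ws) slowPend[i] = 0.0;  // refractory at instant end: no slow input
    }
}
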