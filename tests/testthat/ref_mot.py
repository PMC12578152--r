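"""Reference CLEAR-MOT / IDF1 implementation used as an independent oracle.

Reads two CSV trajectory files (columns frame,id,cx,cy,w,h in center form),
applies the CLEAR-MOT correspondence protocol (previous-frame pairs persist
while IoU >= threshold, remainder matched by scipy's Hungarian solver on
1 - IoU) and the global id-assignment IDF1, and writes a JSON report.
Shares no code with the R package under test.
"""
import json
import sys

import numpy as np
import pandas as pd
from scipy.optimize import linear_sum_assignment


def iou_matrix(a, b):
    ax1 = a.cx.values - a.w.values / 2
    ax2 = a.cx.values + a.w.values / 2
    ay1 = a.cy.values - a.h.values / 2
    ay2 = a.cy.values + a.h.values / 2
    bx1 = b.cx.values - b.w.values / 2
    bx2 = b.cx.values + b.w.values / 2
    by1 = b.cy.values - b.h.values / 2
    by2 = b.cy.values + b.h.values / 2
    iw = np.maximum(
        np.minimum(ax2[:, None], bx2[None, :]) - np.maximum(ax1[:, None], bx1[None, :]), 0
    )
    ih = np.maximum(
        np.minimum(ay2[:, None], by2[None, :]) - np.maximum(ay1[:, None], by1[None, :]), 0
    )
    inter = iw * ih
    areas = (a.w.values * a.h.values)[:, None] + (b.w.values * b.h.values)[None, :]
    return inter / (areas - inter)


def evaluate(gt, hyp, thr):
    frames = sorted(set(gt.frame) | set(hyp.frame))
    prev = {}
    last = {}
    fp = fn = ids = matches = 0
    iou_sum = 0.0
    for f in frames:
        g = gt[gt.frame == f].reset_index(drop=True)
        h = hyp[hyp.frame == f].reset_index(drop=True)
        pairs = []
        if len(g) and len(h):
            iou = iou_matrix(g, h)
            g_free = np.ones(len(g), bool)
            h_free = np.ones(len(h), bool)
            for gid, hid in prev.items():
                gi = np.flatnonzero(g.id.values == gid)
                hi = np.flatnonzero(h.id.values == hid)
                if len(gi) and len(hi) and g_free[gi[0]] and h_free[hi[0]]:
                    if iou[gi[0], hi[0]] >= thr:
                        pairs.append((gi[0], hi[0]))
                        g_free[gi[0]] = h_free[hi[0]] = False
            gi_rest = np.flatnonzero(g_free)
            hi_rest = np.flatnonzero(h_free)
            if len(gi_rest) and len(hi_rest):
                sub = 1 - iou[np.ix_(gi_rest, hi_rest)]
                BIG = 1e9
                sub = np.where(sub > 1 - thr, BIG, sub)
                ri, ci = linear_sum_assignment(sub)
                for r, c in zip(ri, ci):
                    if sub[r, c] < BIG:
                        pairs.append((gi_rest[r], hi_rest[c]))
        fn += len(g) - len(pairs)
        fp += len(h) - len(pairs)
        matches += len(pairs)
        prev = {}
        for gi, hi in pairs:
            gid, hid = g.id.values[gi], h.id.values[hi]
            if gid in last and last[gid] != hid:
                ids += 1
            last[gid] = hid
            prev[gid] = hid
            # recompute overlap for MOTP
            iou_sum += iou_matrix(g.iloc[[gi]], h.iloc[[hi]])[0, 0]
    num_gt = len(gt)
    return {
        "mota": 100 * (1 - (fn + fp + ids) / num_gt),
        "motp": 100 * iou_sum / matches if matches else 0.0,
        "ids": ids,
        "rcll": 100 * (num_gt - fn) / num_gt,
        "prcn": 100 * matches / (matches + fp) if matches + fp else 0.0,
        "idf1": idf1(gt, hyp, thr),
    }


def idf1(gt, hyp, thr):
    g_ids = sorted(set(gt.id))
    h_ids = sorted(set(hyp.id))
    if not h_ids:
        return 0.0
    m = np.zeros((len(g_ids), len(h_ids)))
    for f in sorted(set(gt.frame)):
        g = gt[gt.frame == f].reset_index(drop=True)
        h = hyp[hyp.frame == f].reset_index(drop=True)
        if not len(h):
            continue
        iou = iou_matrix(g, h)
        for a, b in zip(*np.where(iou >= thr)):
            m[g_ids.index(g.id.values[a]), h_ids.index(h.id.values[b])] += 1
    ri, ci = linear_sum_assignment(-m)
    idtp = m[ri, ci].sum()
    return 100 * 2 * idtp / (len(gt) + len(hyp))


if __name__ == "__main__":
    gt_path, hyp_path, thr, out = sys.argv[1:5]
    gt = pd.read_csv(gt_path)
    hyp = pd.read_csv(hyp_path)
    with open(out, "w") as fh:
        json.dump(evaluate(gt, hyp, float(thr)), fh)
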