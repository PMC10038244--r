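#!/usr/bin/env python
"""GeoPackage <-> GeoJSON bridge.

Used by the R package for GeoPackage I/O: R serializes layers as GeoJSON and
this script moves them into/out of a .gpkg (SQLite) container, using the
stdlib sqlite3 module and shapely only for WKB encoding/decoding.

Usage:
  gpkg_io.py read  <file.gpkg> <out.geojson> [layer]
  gpkg_io.py write <in.geojson> <file.gpkg> <layer> <srs_id> <srs_wkt>
"""
import json
import struct
import sqlite3
import sys

from shapely.geometry import shape, mapping
from shapely import wkb as shapely_wkb


def gp_header(srs_id):
    # magic 'GP', version 0, flags 0b00000001 (little-endian, no envelope)
    return b"GP" + bytes([0, 1]) + struct.pack("<i", srs_id)


def parse_gp_blob(blob):
    if blob is None or len(blob) < 8 or blob[:2] != b"GP":
        raise ValueError("not a GeoPackage geometry blob")
    flags = blob[3]
    env_ind = (flags >> 1) & 0x07
    env_len = {0: 0, 1: 32, 2: 48, 3: 48, 4: 64}.get(env_ind, 0)
    return shapely_wkb.loads(bytes(blob[8 + env_len:]))


def read_gpkg(path, out_path, layer=None):
    con = sqlite3.connect(path)
    cur = con.cursor()
    row = None
    if layer:
        row = cur.execute(
            "SELECT table_name, column_name, srs_id FROM gpkg_geometry_columns"
            " WHERE table_name = ?", (layer,)).fetchone()
        if row is None:
            sys.stderr.write("layer not found: %s\n" % layer)
            sys.exit(3)
    else:
        row = cur.execute(
            "SELECT table_name, column_name, srs_id FROM gpkg_geometry_columns"
            " LIMIT 1").fetchone()
        if row is None:
            sys.stderr.write("no feature layers in %s\n" % path)
            sys.exit(3)
    table, gcol, srs_id = row
    epsg = None
    r = cur.execute("SELECT organization, organization_coordsys_id FROM"
                    " gpkg_spatial_ref_sys WHERE srs_id = ?",
                    (srs_id,)).fetchone()
    if r and str(r[0]).upper() == "EPSG":
        epsg = int(r[1])
    cols = [c[1] for c in cur.execute('PRAGMA table_info("%s")' % table)]
    attr_cols = [c for c in cols if c not in (gcol, "fid")]
    sel = ', '.join('"%s"' % c for c in ([gcol] + attr_cols))
    feats = []
    for rec in cur.execute('SELECT %s FROM "%s"' % (sel, table)):
        geom = parse_gp_blob(rec[0]) if rec[0] is not None else None
        props = dict(zip(attr_cols, rec[1:]))
        feats.append({"type": "Feature", "properties": props,
                      "geometry": mapping(geom) if geom is not None else None})
    fc = {"type": "FeatureCollection", "features": feats}
    if epsg:
        fc["crs"] = {"type": "name",
                     "properties": {"name": "urn:ogc:def:crs:EPSG::%d" % epsg}}
    with open(out_path, "w") as fh:
        json.dump(fc, fh)
    con.close()


GPKG_TYPE = {"Point": "POINT", "MultiPoint": "MULTIPOINT",
             "LineString": "LINESTRING", "MultiLineString": "MULTILINESTRING",
             "Polygon": "POLYGON", "MultiPolygon": "MULTIPOLYGON"}


def sql_type(v):
    if isinstance(v, bool):
        return "INTEGER"
    if isinstance(v, int):
        return "INTEGER"
    if isinstance(v, float):
        return "REAL"
    return "TEXT"


def write_gpkg(geojson_path, path, layer, srs_id, srs_wkt):
    with open(geojson_path) as fh:
        fc = json.load(fh)
    feats = fc.get("features", [])
    import os
    if os.path.exists(path):
        os.remove(path)
    con = sqlite3.connect(path)
    cur = con.cursor()
    cur.execute("PRAGMA application_id = 0x47504B47")
    cur.execute("PRAGMA user_version = 10300")
    cur.execute("""CREATE TABLE gpkg_spatial_ref_sys (
        srs_name TEXT NOT NULL, srs_id INTEGER NOT NULL PRIMARY KEY,
        organization TEXT NOT NULL, organization_coordsys_id INTEGER NOT NULL,
        definition TEXT NOT NULL, description TEXT)""")
    cur.executemany(
        "INSERT INTO gpkg_spatial_ref_sys VALUES (?,?,?,?,?,?)",
        [("Undefined cartesian", -1, "NONE", -1, "undefined", None),
         ("Undefined geographic", 0, "NONE", 0, "undefined", None)])
    if srs_id not in (-1, 0):
        cur.execute("INSERT INTO gpkg_spatial_ref_sys VALUES (?,?,?,?,?,?)",
                    ("EPSG:%d" % srs_id, srs_id, "EPSG", srs_id, srs_wkt, None))
    cur.execute("""CREATE TABLE gpkg_contents (
        table_name TEXT NOT NULL PRIMARY KEY, data_type TEXT NOT NULL,
        identifier TEXT UNIQUE, description TEXT DEFAULT '',
        last_change DATETIME NOT NULL DEFAULT
          (strftime('%Y-%m-%dT%H:%M:%fZ','now')),
        min_x DOUBLE, min_y DOUBLE, max_x DOUBLE, max_y DOUBLE,
        srs_id INTEGER)""")
    cur.execute("""CREATE TABLE gpkg_geometry_columns (
        table_name TEXT NOT NULL PRIMARY KEY, column_name TEXT NOT NULL,
        geometry_type_name TEXT NOT NULL, srs_id INTEGER NOT NULL,
        z TINYINT NOT NULL, m TINYINT NOT NULL)""")

    shapes = [shape(f["geometry"]) if f.get("geometry") else None
              for f in feats]
    gtype = "GEOMETRY"
    for s in shapes:
        if s is not None:
            gtype = GPKG_TYPE.get(s.geom_type, "GEOMETRY")
            break
    attr_names = []
    for f in feats:
        for k in (f.get("properties") or {}):
            if k not in attr_names:
                attr_names.append(k)
    attr_types = {}
    for nm in attr_names:
        t = "TEXT"
        for f in feats:
            v = (f.get("properties") or {}).get(nm)
            if v is not None:
                t = sql_type(v)
                break
        attr_types[nm] = t
    cols = ", ".join('"%s" %s' % (nm, attr_types[nm]) for nm in attr_names)
    cur.execute('CREATE TABLE "%s" (fid INTEGER PRIMARY KEY AUTOINCREMENT,'
                ' geom BLOB%s)' % (layer, (", " + cols) if cols else ""))
    bbox = [None, None, None, None]
    for f, s in zip(feats, shapes):
        blob = None
        if s is not None:
            blob = gp_header(srs_id) + shapely_wkb.dumps(s)
            b = s.bounds
            bbox[0] = b[0] if bbox[0] is None else min(bbox[0], b[0])
            bbox[1] = b[1] if bbox[1] is None else min(bbox[1], b[1])
            bbox[2] = b[2] if bbox[2] is None else max(bbox[2], b[2])
            bbox[3] = b[3] if bbox[3] is None else max(bbox[3], b[3])
        props = f.get("properties") or {}
        vals = [props.get(nm) for nm in attr_names]
        ph = ", ".join(["?"] * (1 + len(attr_names)))
        cur.execute('INSERT INTO "%s" (geom%s) VALUES (%s)' %
                    (layer, ("".join(', "%s"' % nm for nm in attr_names)), ph),
                    [blob] + vals)
    cur.execute("INSERT INTO gpkg_contents (table_name, data_type, identifier,"
                " min_x, min_y, max_x, max_y, srs_id)"
                " VALUES (?,?,?,?,?,?,?,?)",
                (layer, "features", layer, bbox[0], bbox[1], bbox[2], bbox[3],
                 srs_id))
    cur.execute("INSERT INTO gpkg_geometry_columns VALUES (?,?,?,?,0,0)",
                (layer, "geom", gtype, srs_id))
    con.commit()
    con.close()


def main(argv):
    if len(argv) < 2:
        sys.stderr.write(__doc__)
        return 2
    mode = argv[1]
    if mode == "read":
        read_gpkg(argv[2], argv[3], argv[4] if len(argv) > 4 else None)
    elif mode == "write":
        write_gpkg(argv[2], argv[3], argv[4], int(argv[5]), argv[6])
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
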