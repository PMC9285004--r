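# HDF5 lives in the same prefix as this R installation (R_HOME = <prefix>/lib/R).
PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(PREFIX)/include
PKG_LIBS = -L$(PREFIX)/lib -Wl,-rpath,$(PREFIX)/lib -lhdf5
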