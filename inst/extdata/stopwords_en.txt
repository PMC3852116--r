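# Standard English closed-class stop words used by the corpus perturbations.
a
an
the
of
in
on
at
by
to
for
with
from
as
and
or
but
this
that
these
those
its
their
is
are
was
were
be
been
which
who
what
when
where
how
not
no
all
some
such
into
through
during
between
under
over
about
after
before
both
each
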